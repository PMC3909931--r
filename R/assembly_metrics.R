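#' N50 of a set of contig lengths
#'
#' The largest length L such that contigs of length >= L together contain
#' at least half of the total assembly length. Equivalently: sort lengths
#' in decreasing order, accumulate, and return the length at which the
#' running sum first reaches total/2. When the running sum hits exactly
#' total/2 that contig's length is the N50 (the >= convention).
#'
#' @param lengths Non-empty vector of positive integer contig lengths.
#' @return A single integer length (always one of the input lengths).
#' @examples
#' n50(c(3, 3, 2, 2, 2))  # total 12; 3 + 3 = 6 >= 6, so N50 = 3
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0L) stop("n50: empty length list")
  if (any(is.na(lengths)) || any(lengths <= 0)) {
    stop("n50: lengths must be positive and non-missing")
  }
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  half <- sum(s) / 2
  idx <- which(cumsum(s) >= half)[1L]
  as.integer(s[idx])
}

#' Assembly summary statistics
#'
#' @param contigs A named \code{DNAStringSet} (from \code{\link{read_fasta}})
#'   or a vector of contig lengths.
#' @param breaks Histogram bin edges (non-decreasing). Bins are closed-open
#'   \code{[lower, upper)} except the last, which is closed, so counts are
#'   bit-reproducible. Lengths outside the edges are not counted but are
#'   reported via \code{n_outside}.
#' @return A list of class \code{assembly_stats}: \code{n_contigs},
#'   \code{total_length}, \code{n50}, \code{mean_length},
#'   \code{length_histogram} (data.frame lower/upper/count),
#'   \code{n_outside}.
#' @export
assembly_stats <- function(contigs, breaks = c(0, 500, 1000, 2000, 5000, Inf)) {
  lens <- contig_lengths(contigs)
  if (length(breaks) < 2L || is.unsorted(breaks)) {
    stop("breaks must be a non-decreasing vector of length >= 2")
  }
  counts <- .bin_counts(lens, breaks)
  structure(list(
    n_contigs = length(lens),
    total_length = sum(lens),
    n50 = n50(lens),
    mean_length = mean(lens),
    length_histogram = data.frame(
      lower = breaks[-length(breaks)],
      upper = breaks[-1L],
      count = counts
    ),
    n_outside = length(lens) - sum(counts)
  ), class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat("assembly_stats\n")
  cat("  contigs:      ", x$n_contigs, "\n")
  cat("  total length: ", x$total_length, "nt\n")
  cat("  N50:          ", x$n50, "nt\n")
  cat("  mean length:  ", round(x$mean_length, 1), "nt\n")
  invisible(x)
}

# [lower, upper) bins, last bin closed on the right
.bin_counts <- function(x, breaks) {
  k <- length(breaks) - 1L
  counts <- integer(k)
  for (i in seq_len(k)) {
    if (i < k) {
      counts[i] <- sum(x >= breaks[i] & x < breaks[i + 1L])
    } else {
      counts[i] <- sum(x >= breaks[i] & x <= breaks[i + 1L])
    }
  }
  counts
}

contig_lengths <- function(contigs) {
  if (methods::is(contigs, "XStringSet")) {
    Biostrings::width(contigs)
  } else if (is.numeric(contigs)) {
    as.numeric(contigs)
  } else {
    stop("contigs must be an XStringSet or a numeric vector of lengths")
  }
}

#' Homology-hit rate stratified by contig length
#'
#' Tallies, per length bin, how many contigs do and do not carry at least
#' one homology hit. Also reports the fraction of the no-hit class that
#' falls in a caller-named focus bin (short contigs typically dominate the
#' no-hit class, and this fraction quantifies that).
#'
#' @param contigs Named \code{DNAStringSet} or named numeric vector of
#'   lengths.
#' @param hit_flags Named logical vector: does each contig have >= 1 hit?
#'   Every contig must be present.
#' @param breaks Length-bin edges, as in \code{\link{assembly_stats}}.
#' @param focus_bin Integer index of the bin whose share of the no-hit
#'   class is reported (default 1, usually the shortest-contig bin).
#' @return A list: \code{table} (data.frame bin lower/upper,
#'   \code{n_with_hit}, \code{n_without_hit}), and
#'   \code{no_hit_focus_fraction} — the fraction of no-hit contigs in the
#'   focus bin, or \code{NA} when there are no no-hit contigs (absent, not
#'   zero: the fraction is undefined for an empty class).
#' @export
hit_rate_by_length <- function(contigs, hit_flags, breaks, focus_bin = 1L) {
  if (length(breaks) < 2L) stop("need at least one length bin")
  lens <- contig_lengths(contigs)
  ids <- names(contigs)
  if (is.null(ids)) stop("contigs must be named")
  missing <- setdiff(ids, names(hit_flags))
  if (length(missing)) {
    stop("contig(s) missing from hit_flags: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  flags <- hit_flags[ids]
  with_hit <- .bin_counts(lens[flags], breaks)
  without_hit <- .bin_counts(lens[!flags], breaks)
  n_nohit <- sum(!flags)
  focus_fraction <- if (n_nohit == 0L) NA_real_ else {
    .bin_counts(lens[!flags], breaks)[focus_bin] / n_nohit
  }
  list(
    table = data.frame(
      lower = breaks[-length(breaks)],
      upper = breaks[-1L],
      n_with_hit = with_hit,
      n_without_hit = without_hit
    ),
    no_hit_focus_fraction = focus_fraction
  )
}
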