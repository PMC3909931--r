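#' Nominal fold-coverage of a contig
#'
#' A depth proxy that needs no base-level pileup: the number of reads
#' aligned to a contig times the (fixed) read length, divided by the contig
#' length. With 40 nt reads, 250 reads on a 1,000 nt contig give 10-fold
#' nominal coverage.
#'
#' @param n_aligned_reads Number of reads aligned to the contig (>= 0).
#' @param read_length Read length in nt (> 0; reads are assumed
#'   fixed-length).
#' @param contig_length Contig length in nt (> 0).
#' @return Nominal fold-coverage (vectorised over its arguments).
#' @export
nominal_coverage <- function(n_aligned_reads, read_length, contig_length) {
  if (any(contig_length <= 0)) stop("contig_length must be > 0")
  if (any(read_length <= 0)) stop("read_length must be > 0")
  if (any(n_aligned_reads < 0)) stop("n_aligned_reads must be >= 0")
  n_aligned_reads * read_length / contig_length
}

# Derive a stream seed (< 2^31) from a master seed and a purpose string.
# Documented scheme: polynomial hash of the purpose string (base 31,
# mod 2^31 - 1) mixed with the master seed. All arithmetic stays exact in
# doubles (< 2^53).
derive_seed <- function(seed, purpose) {
  m <- 2147483647
  h <- (as.numeric(seed) %% m)
  for (cc in utf8ToInt(purpose)) h <- (h * 31 + cc) %% m
  as.integer(h)
}

# Evaluate code under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Subsample alignment records without replacement
#'
#' Draws exactly \code{n} records uniformly at random, without replacement,
#' from the full pool of sequencing records — aligned and unaligned alike,
#' because sequencing depth is measured in total reads, not aligned reads.
#' The draw is a pure function of \code{seed}.
#'
#' @param alignments data.frame of alignment records
#'   (\code{\link{read_sam}} output).
#' @param n Number of records to draw (0 <= n <= nrow).
#' @param seed Integer seed; identical seeds give identical samples.
#' @return A data.frame of exactly \code{n} records.
#' @export
subsample_alignments <- function(alignments, n, seed) {
  total <- nrow(alignments)
  if (n < 0 || n > total) {
    stop("subset size ", n, " outside [0, ", total, "]")
  }
  if (n == 0L) return(alignments[integer(0), , drop = FALSE])
  idx <- with_seed(seed, sample.int(total, n, replace = FALSE))
  out <- alignments[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Per-contig aligned-record counts for a set of alignment records, in the
# order of `ids`. Unaligned records (reference_id NA) contribute nowhere.
aligned_counts <- function(alignments, ids) {
  ref <- alignments$reference_id
  ref <- ref[!is.na(ref)]
  unknown <- setdiff(unique(ref), ids)
  if (length(unknown)) {
    stop("alignment(s) reference unknown contig(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  tab <- table(factor(ref, levels = ids))
  as.integer(tab)
}

# Multivariate hypergeometric draw: how many of each contig's aligned
# records land in a subsample of size n from a pool of `total` records,
# where contig i has counts[i] aligned records. Sequential conditional
# univariate hypergeometric draws.
rmvhyper_counts <- function(counts, total, n) {
  k <- length(counts)
  out <- integer(k)
  rest <- total
  left <- n
  for (i in seq_len(k)) {
    if (left == 0L) break
    out[i] <- stats::rhyper(1L, counts[i], rest - counts[i], left)
    rest <- rest - counts[i]
    left <- left - out[i]
  }
  out
}

#' Sequencing saturation curve by alignment subsampling
#'
#' For each subset size, repeatedly subsamples the full pool of sequencing
#' records without replacement, computes each contig's nominal coverage
#' from the subsample, and records the fraction of contigs at or above the
#' coverage threshold. Replicate seeds are derived deterministically from
#' the master seed and the (size, replicate) indices, so any point of the
#' curve can be recomputed in isolation.
#'
#' @param alignments data.frame of alignment records (aligned + unaligned;
#'   \code{\link{read_sam}} output). All aligned records must reference a
#'   contig present in \code{contigs}.
#' @param contigs Named \code{DNAStringSet} or named numeric lengths.
#' @param read_length Read length in nt.
#' @param threshold Fold-coverage threshold (> 0); the curve reports the
#'   fraction of contigs with nominal coverage >= threshold.
#' @param subset_sizes Integer vector of subsample sizes (each <= total
#'   record count).
#' @param replicates Replicates per subset size (>= 1). Subset sizes 0 and
#'   the full pool are deterministic, so a single replicate is computed for
#'   them and the sd is 0 by construction.
#' @param seed Master integer seed.
#' @param method \code{"records"} draws record indices (reference
#'   behaviour); \code{"counts"} draws per-contig aligned counts directly
#'   from the equivalent multivariate hypergeometric — distributionally
#'   identical and much faster for large pools.
#' @return data.frame of class \code{saturation_curve}: one row per subset
#'   size with \code{n_reads}, \code{mean_fraction_covered},
#'   \code{sd_fraction_covered} (sample sd, n-1 denominator) and a list
#'   column \code{per_replicate_fractions}.
#' @export
saturation_curve <- function(alignments, contigs, read_length, threshold,
                             subset_sizes, replicates = 3L, seed = 1L,
                             method = c("records", "counts")) {
  method <- match.arg(method)
  if (threshold <= 0) stop("coverage threshold must be > 0")
  if (replicates < 1L) stop("replicates must be >= 1")
  lens <- contig_lengths(contigs)
  ids <- names(contigs)
  if (is.null(ids)) stop("contigs must be named")
  total <- nrow(alignments)
  if (any(subset_sizes < 0 | subset_sizes > total)) {
    stop("subset sizes must lie in [0, ", total, "]")
  }
  base_counts <- aligned_counts(alignments, ids)

  frac_from_counts <- function(counts) {
    mean(nominal_coverage(counts, read_length, lens) >= threshold)
  }

  rows <- lapply(subset_sizes, function(sz) {
    deterministic <- sz == 0L || sz == total
    nrep <- if (deterministic) 1L else replicates
    fr <- vapply(seq_len(nrep), function(r) {
      s <- derive_seed(seed, paste("saturation", sz, r, sep = ":"))
      cnt <- if (sz == 0L) {
        integer(length(ids))
      } else if (sz == total) {
        base_counts
      } else if (method == "records") {
        sub <- subsample_alignments(alignments, sz, s)
        aligned_counts(sub, ids)
      } else {
        with_seed(s, rmvhyper_counts(base_counts, total, sz))
      }
      frac_from_counts(cnt)
    }, numeric(1))
    if (deterministic) fr <- rep(fr, replicates)
    data.frame(
      n_reads = sz,
      mean_fraction_covered = mean(fr),
      sd_fraction_covered = if (length(fr) > 1L) stats::sd(fr) else 0,
      per_replicate_fractions = I(list(fr))
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("saturation_curve", class(out))
  out
}

#' Write a saturation curve as TSV
#' @param curve \code{\link{saturation_curve}} output.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_saturation_tsv <- function(curve, path) {
  flat <- data.frame(
    n_reads = curve$n_reads,
    mean_fraction_covered = curve$mean_fraction_covered,
    sd_fraction_covered = curve$sd_fraction_covered,
    per_replicate_fractions = vapply(
      curve$per_replicate_fractions,
      function(v) paste(format(v, digits = 10), collapse = ","),
      character(1))
  )
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
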