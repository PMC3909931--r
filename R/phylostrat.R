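#' Build a lineage model for phylostratigraphic assignment
#'
#' A lineage model orders taxonomic bins from the closest relative of the
#' focal species outward, and maps each bin to the ancestral branch a hit
#' in that bin (and none deeper) implies. Bins off the descent path
#' (e.g. viruses) are listed separately: a hit there never defines an
#' ancestor.
#'
#' @param bins Character vector of in-lineage bin names, ordered from most
#'   recently diverged (closest to the focal species) to most distant.
#' @param ancestors Character vector of ancestral-branch labels, parallel
#'   to \code{bins}: the origin assigned when \code{bins[i]} is the deepest
#'   bin with a hit.
#' @param out_of_lineage Bin names outside the lineage (default none).
#' @param focal_name Name of the focal species (informational).
#' @param distal_bins Bins counted as "distal" by the contamination
#'   heuristic (default: none; see \code{\link{edwardsiid_lineage_model}}
#'   for a populated example).
#' @param intermediate_bins Bins whose emptiness the contamination
#'   heuristic requires (default: none).
#' @return An object of class \code{lineage_model}.
#' @seealso \code{\link{assign_origin}}, \code{\link{flag_contamination}}
#' @export
lineage_model <- function(bins, ancestors, out_of_lineage = character(),
                          focal_name = "focal species",
                          distal_bins = character(),
                          intermediate_bins = character()) {
  if (length(bins) == 0L) stop("ordered bin list must be non-empty")
  if (length(bins) != length(ancestors)) {
    stop("bins and ancestors must be parallel vectors")
  }
  all_bins <- c(bins, out_of_lineage)
  if (anyDuplicated(all_bins)) {
    stop("bin names must be unique across in-lineage and out-of-lineage lists")
  }
  bad <- setdiff(c(distal_bins, intermediate_bins), all_bins)
  if (length(bad)) stop("unknown bin(s) in heuristic sets: ",
                        paste(bad, collapse = ", "))
  structure(list(
    bins = bins, ancestors = ancestors,
    out_of_lineage = out_of_lineage,
    focal_name = focal_name,
    distal_bins = distal_bins,
    intermediate_bins = intermediate_bins
  ), class = "lineage_model")
}

#' The edwardsiid anemone eight-bin lineage model
#'
#' The canonical model for an edwardsiid sea anemone transcriptome
#' annotated against taxonomically restricted protein sets: seven nested
#' in-lineage bins from the confamilial anemone \emph{N. vectensis} out to
#' Eubacteria, plus viruses as an out-of-lineage bin. Archaea and
#' Eubacteria carry distinct ancestor labels by default;
#' \code{merge_prokaryote_ancestors = TRUE} collapses both onto a single
#' cellular-ancestor label for summaries that pool the deepest strata.
#'
#' The contamination heuristic's default sets are: distal = the two
#' prokaryote bins plus viruses; intermediate = Bilateria, basal Metazoa
#' and non-metazoan Eukaryota (the bins between the cnidarian bins and the
#' prokaryotes).
#'
#' @param merge_prokaryote_ancestors Collapse the Archaea and Eubacteria
#'   strata onto one "ancestor of cellular life" label.
#' @return A \code{\link{lineage_model}}.
#' @export
edwardsiid_lineage_model <- function(merge_prokaryote_ancestors = FALSE) {
  bins <- c("N. vectensis",
            "Cnidaria excluding N. vectensis",
            "Bilateria",
            "Metazoa excluding Cnidaria and Bilateria",
            "Eukaryota excluding Metazoa",
            "Archaea",
            "Eubacteria")
  ancestors <- c("Edwardsiidae ancestor",
                 "Cnidaria ancestor",
                 "Eumetazoa ancestor",
                 "Metazoa ancestor",
                 "Eukaryota ancestor",
                 "ancestor of Archaea + Eukaryota",
                 "ancestor of Eubacteria + Eukaryota")
  if (merge_prokaryote_ancestors) {
    ancestors[6:7] <- "ancestor of cellular life"
  }
  lineage_model(
    bins, ancestors,
    out_of_lineage = "viruses",
    focal_name = "E. lineata",
    distal_bins = c("Archaea", "Eubacteria", "viruses"),
    intermediate_bins = c("Bilateria",
                          "Metazoa excluding Cnidaria and Bilateria",
                          "Eukaryota excluding Metazoa")
  )
}

#' @export
print.lineage_model <- function(x, ...) {
  cat("lineage_model for", x$focal_name, "\n")
  for (i in seq_along(x$bins)) {
    cat(sprintf("  %d. %-42s -> %s\n", i, x$bins[i], x$ancestors[i]))
  }
  if (length(x$out_of_lineage)) {
    cat("  out of lineage:", paste(x$out_of_lineage, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a lineage model from a TSV config file
#'
#' The file holds ordered \code{bin<TAB>ancestor_label} lines (closest bin
#' first); an optional \code{[out_of_lineage]} section lists off-lineage
#' bins one per line. Optional \code{[distal]} and \code{[intermediate]}
#' sections configure the contamination heuristic (defaults when absent:
#' distal = the last in-lineage bin plus all out-of-lineage bins;
#' intermediate = every in-lineage bin strictly between the second bin and
#' the distal bins).
#'
#' @param path Path to the config file.
#' @param focal_name Focal species name.
#' @return A \code{\link{lineage_model}}.
#' @export
read_lineage_model <- function(path, focal_name = "focal species") {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  section <- "bins"
  bins <- character(); ancestors <- character()
  ool <- character(); distal <- character(); intermediate <- character()
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      next
    }
    if (section == "bins") {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
      if (length(parts) < 2L) {
        stop("lineage model line needs bin<TAB>ancestor_label: '", ln, "'")
      }
      bins <- c(bins, parts[1L]); ancestors <- c(ancestors, parts[2L])
    } else if (section == "out_of_lineage") {
      ool <- c(ool, ln)
    } else if (section == "distal") {
      distal <- c(distal, ln)
    } else if (section == "intermediate") {
      intermediate <- c(intermediate, ln)
    } else {
      stop("unknown section [", section, "] in lineage model file")
    }
  }
  if (length(bins) == 0L) stop("no bins in lineage model file")
  if (length(distal) == 0L) distal <- c(bins[length(bins)], ool)
  if (length(intermediate) == 0L && length(bins) > 2L) {
    intermediate <- setdiff(bins[3:length(bins)], distal)
  }
  lineage_model(bins, ancestors, out_of_lineage = ool,
                focal_name = focal_name, distal_bins = distal,
                intermediate_bins = intermediate)
}

#' Write a lineage model to its TSV config format
#' @param model A \code{\link{lineage_model}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_lineage_model <- function(model, path) {
  out <- c(paste(model$bins, model$ancestors, sep = "\t"))
  if (length(model$out_of_lineage)) {
    out <- c(out, "[out_of_lineage]", model$out_of_lineage)
  }
  if (length(model$distal_bins)) out <- c(out, "[distal]", model$distal_bins)
  if (length(model$intermediate_bins)) {
    out <- c(out, "[intermediate]", model$intermediate_bins)
  }
  writeLines(out, path)
  invisible(path)
}

.check_bins <- function(hit_bins, model) {
  known <- c(model$bins, model$out_of_lineage)
  bad <- setdiff(hit_bins, known)
  if (length(bad)) {
    stop("unknown taxonomic bin(s): ", paste(bad, collapse = ", "))
  }
}

#' Contamination heuristic for one contig's hit pattern
#'
#' A contig whose hits are confined to distal lineages, with none in the
#' intermediate lineages that separate the focal clade from those distal
#' groups, more plausibly derives from a contaminating organism (whose
#' relatives are well represented in the database) than from a gene
#' conserved across that whole span. The flag is advisory: it never
#' changes the origin assignment.
#'
#' @param hit_bins Character vector (treated as a set) of bins with >= 1
#'   hit for the contig.
#' @param model A \code{\link{lineage_model}} with \code{distal_bins} and
#'   \code{intermediate_bins} configured.
#' @return TRUE iff the deepest hit bin is distal and no intermediate bin
#'   has a hit. Contigs with no hits are never flagged.
#' @export
flag_contamination <- function(hit_bins, model) {
  .check_bins(hit_bins, model)
  hit_bins <- unique(hit_bins)
  if (length(hit_bins) == 0L) return(FALSE)
  if (length(model$distal_bins) == 0L) return(FALSE)
  in_lineage <- intersect(model$bins, hit_bins)
  deepest <- if (length(in_lineage)) {
    model$bins[max(match(in_lineage, model$bins))]
  } else {
    # out-of-lineage-only pattern: treat as distal when those bins are
    hit_bins[1L]
  }
  deepest_distal <- deepest %in% model$distal_bins ||
    (length(in_lineage) == 0L && all(hit_bins %in% model$distal_bins))
  deepest_distal && !any(model$intermediate_bins %in% hit_bins)
}

#' Assign a phylostratigraphic origin from a contig's hit pattern
#'
#' Deepest-hit-wins: the in-lineage bin furthest from the focal species
#' that has at least one hit sets the inferred ancestral origin. A contig
#' hit only in out-of-lineage bins (e.g. viruses) gets the sentinel class
#' \code{out_of_lineage_only}; a contig with no hits at all gets
#' \code{no_hit}. Out-of-lineage hits are ignored whenever any in-lineage
#' hit exists. The contamination heuristic runs on the same pattern and is
#' reported alongside, never overriding the origin.
#'
#' @param hit_bins Character vector (a set) of bins with >= 1 hit.
#' @param model A \code{\link{lineage_model}}.
#' @return A list of class \code{origin_assignment}: \code{origin_label},
#'   \code{deepest_bin} (NA for no_hit / out_of_lineage_only),
#'   \code{contamination_flag}, \code{hit_bins}.
#' @examples
#' m <- edwardsiid_lineage_model()
#' assign_origin("N. vectensis", m)$origin_label   # confamilial-only class
#' assign_origin(character(), m)$origin_label      # "no_hit"
#' @export
assign_origin <- function(hit_bins, model) {
  .check_bins(hit_bins, model)
  hit_bins <- unique(hit_bins)
  in_lineage <- intersect(model$bins, hit_bins)
  if (length(hit_bins) == 0L) {
    label <- "no_hit"; deepest <- NA_character_
  } else if (length(in_lineage) == 0L) {
    label <- "out_of_lineage_only"; deepest <- NA_character_
  } else {
    di <- max(match(in_lineage, model$bins))
    deepest <- model$bins[di]
    label <- model$ancestors[di]
  }
  structure(list(
    origin_label = label,
    deepest_bin = deepest,
    contamination_flag = flag_contamination(hit_bins, model),
    hit_bins = hit_bins
  ), class = "origin_assignment")
}

#' Assign origins for every contig in a set of hit tables
#'
#' @param hits data.frame of hit records (rows from \code{\link{read_hits}}
#'   over all bins, concatenated).
#' @param model A \code{\link{lineage_model}}.
#' @param contig_ids Optional character vector of all contig ids; contigs
#'   absent from \code{hits} are assigned \code{no_hit}. Default: the
#'   contigs present in \code{hits}.
#' @return data.frame with one row per contig: \code{contig_id},
#'   \code{origin_label}, \code{deepest_bin}, \code{contamination_flag},
#'   \code{hit_bins} (comma-joined).
#' @export
assign_origins <- function(hits, model, contig_ids = NULL) {
  .check_bins(unique(hits$bin), model)
  by_contig <- split(hits$bin, hits$query_id)
  if (is.null(contig_ids)) contig_ids <- names(by_contig)
  rows <- lapply(contig_ids, function(id) {
    bins <- unique(by_contig[[id]])
    if (is.null(bins)) bins <- character()
    a <- assign_origin(bins, model)
    data.frame(contig_id = id,
               origin_label = a$origin_label,
               deepest_bin = a$deepest_bin,
               contamination_flag = a$contamination_flag,
               hit_bins = paste(sort(bins), collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Summarise origin assignments into strata counts and percentages
#'
#' Percentages are taken over hit-producing contigs only (the conventional
#' denominator for phylostratigraphic summaries: contigs without homology
#' hits carry no origin signal). \code{no_hit} and
#' \code{out_of_lineage_only} contigs and contamination flags are counted
#' separately.
#'
#' @param assignments data.frame from \code{\link{assign_origins}}.
#' @param model A \code{\link{lineage_model}} (fixes stratum order in the
#'   output).
#' @return A list of class \code{stratum_summary}: \code{strata}
#'   (data.frame ancestor_label / count / percent, one row per ancestor
#'   label plus an \code{out_of_lineage_only} row, percent NA when no
#'   contig produced a hit), \code{n_hit_producing}, \code{n_no_hit},
#'   \code{n_out_of_lineage_only}, \code{n_contamination_flagged}.
#' @export
summarize_strata <- function(assignments, model) {
  if (nrow(assignments) == 0L) stop("no assignments to summarise")
  labels <- unique(model$ancestors)
  n_ool <- sum(assignments$origin_label == "out_of_lineage_only")
  if (length(model$out_of_lineage) || n_ool > 0L) {
    labels <- c(labels, "out_of_lineage_only")
  }
  is_stratum <- assignments$origin_label %in% labels
  counts <- vapply(labels, function(l) {
    sum(assignments$origin_label == l)
  }, integer(1))
  denom <- sum(is_stratum)
  pct <- if (denom == 0L) rep(NA_real_, length(labels)) else 100 * counts / denom
  structure(list(
    strata = data.frame(ancestor_label = labels, count = counts,
                        percent = pct, stringsAsFactors = FALSE,
                        row.names = NULL),
    n_hit_producing = denom,
    n_no_hit = sum(assignments$origin_label == "no_hit"),
    n_out_of_lineage_only = n_ool,
    n_contamination_flagged = sum(assignments$contamination_flag)
  ), class = "stratum_summary")
}

#' @export
print.stratum_summary <- function(x, ...) {
  cat("stratum_summary:", x$n_hit_producing, "hit-producing contigs;",
      x$n_no_hit, "no-hit;", x$n_out_of_lineage_only, "out-of-lineage-only;",
      x$n_contamination_flagged, "contamination-flagged\n")
  df <- x$strata
  df$percent <- round(df$percent, 1)
  print(df, row.names = FALSE)
  invisible(x)
}
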