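#' BLOSUM62 with punitive stop-codon scores
#'
#' The standard BLOSUM62 matrix (as shipped with Biostrings) with the stop
#' symbol \code{*} re-scored to the matrix minimum against every residue,
#' itself included. In translated searches this prevents alignments that
#' read through a stop codon from outscoring honest in-frame matches.
#'
#' @return A numeric substitution matrix with dimnames over the amino-acid
#'   alphabet including \code{X} and \code{*}.
#' @export
blosum62_stop <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  worst <- min(m)
  m["*", ] <- worst
  m[, "*"] <- worst
  m
}

#' Translate a nucleotide sequence in all six reading frames
#'
#' Three forward frames and three frames of the reverse complement, under
#' the standard genetic code. Ambiguous codons translate to \code{X};
#' stop codons are emitted as \code{*} (frames are not split at stops at
#' this layer — that is the aligner's concern). Trailing partial codons
#' are dropped.
#'
#' @param sequence A single IUPAC nucleotide string or \code{DNAString}.
#' @return Named character vector of 6 peptides
#'   (\code{F1,F2,F3,R1,R2,R3}); frames too short for one codon are empty
#'   strings.
#' @examples
#' six_frame_translate("ATGGCC")[["F1"]]  # "MA"
#' @export
six_frame_translate <- function(sequence) {
  s <- Biostrings::DNAString(as.character(sequence))  # errors on non-IUPAC
  rc <- Biostrings::reverseComplement(s)
  one <- function(x, off) {
    n <- length(x) - off
    n <- n - (n %% 3L)
    if (n < 3L) return("")
    as.character(Biostrings::translate(
      Biostrings::subseq(x, start = off + 1L, width = n),
      if.fuzzy.codon = "X"))
  }
  c(F1 = one(s, 0L), F2 = one(s, 1L), F3 = one(s, 2L),
    R1 = one(rc, 0L), R2 = one(rc, 1L), R3 = one(rc, 2L))
}

#' Smith-Waterman local alignment of two peptides
#'
#' Affine-gap local alignment: a gap of length L costs
#' \code{gap_open + L * gap_extend}. The score is floored at zero (the
#' empty alignment), so two peptides with no positively scoring residue
#' pair score 0. Defaults follow protein-BLAST conventions: BLOSUM62,
#' gap open 11, gap extend 1.
#'
#' @param a,b Peptide strings (may be empty).
#' @param matrix Substitution matrix with residue dimnames covering every
#'   residue in \code{a} and \code{b}.
#' @param gap_open,gap_extend Affine gap parameters (>= 0).
#' @return A list: \code{score}, and 1-based span coordinates
#'   \code{a_start}, \code{a_end}, \code{b_start}, \code{b_end} (NA when
#'   the best local score is 0).
#' @export
local_align <- function(a, b, matrix = blosum62_stop(),
                        gap_open = 11, gap_extend = 1) {
  residues <- rownames(matrix)
  if (is.null(residues) || !identical(residues, colnames(matrix))) {
    stop("substitution matrix needs identical row/col residue dimnames")
  }
  encode <- function(p) {
    if (nchar(p) == 0L) return(integer(0))
    ch <- strsplit(p, "", fixed = TRUE)[[1L]]
    idx <- match(ch, residues)
    if (anyNA(idx)) {
      stop("residue(s) missing from substitution matrix: ",
           paste(unique(ch[is.na(idx)]), collapse = ", "))
    }
    idx - 1L
  }
  sw_align_idx(encode(a), encode(b), matrix, gap_open, gap_extend)
}

#' Built-in translated-search backend
#'
#' A search backend over the package's own six-frame translation and
#' Smith-Waterman scoring, so the reciprocal recovery protocol runs with
#' no external search tool. A nucleotide sequence scores against a protein
#' as the maximum local-alignment score over its six frames. E-values are
#' not computed: raw scores suffice for ranking, which is all the
#' protocol needs. External search tools can be wrapped behind the same
#' contract (a function of \code{(queries, subjects, mode)} returning
#' ranked hits).
#'
#' @param matrix Substitution matrix (default \code{\link{blosum62_stop}}).
#' @param gap_open,gap_extend Affine gap parameters.
#' @return A function \code{(queries, subjects, mode)} returning a
#'   data.frame (\code{query_id}, \code{subject_id}, \code{score}) sorted
#'   per query by descending score, ties broken by subject id. Modes:
#'   \code{"protein-vs-translated-nucleotide"} (protein queries, contig
#'   subjects) and \code{"nucleotide-translated-vs-protein"}.
#' @export
builtin_search_backend <- function(matrix = blosum62_stop(),
                                   gap_open = 11, gap_extend = 1) {
  score_pep_vs_contig <- function(pep, contig) {
    frames <- six_frame_translate(contig)
    max(vapply(frames, function(f) {
      local_align(pep, f, matrix, gap_open, gap_extend)$score
    }, numeric(1)))
  }
  function(queries, subjects,
           mode = c("protein-vs-translated-nucleotide",
                    "nucleotide-translated-vs-protein")) {
    mode <- match.arg(mode)
    qs <- as.character(queries); names(qs) <- names(queries)
    ss <- as.character(subjects); names(ss) <- names(subjects)
    if (is.null(names(qs)) || is.null(names(ss))) {
      stop("queries and subjects must be named")
    }
    rows <- lapply(names(qs), function(q) {
      sc <- vapply(names(ss), function(s) {
        if (mode == "protein-vs-translated-nucleotide") {
          score_pep_vs_contig(qs[[q]], ss[[s]])
        } else {
          score_pep_vs_contig(ss[[s]], qs[[q]])
        }
      }, numeric(1))
      ord <- order(-sc, names(ss))
      data.frame(query_id = q, subject_id = names(ss)[ord],
                 score = sc[ord], stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    out
  }
}

#' Reciprocal-search recovery of gene family members
#'
#' The two-step protocol for recovering members of known gene families
#' from a transcriptome assembly: (1) each reference protein queries the
#' transcriptome in translated mode and up to \code{top_k} hits scoring at
#' least \code{min_score} are retained as candidates; (2) each candidate
#' transcript is searched (translated) back against the full reference
#' protein set, and the candidate is verified iff its reciprocal top hit
#' is the original query protein. Reciprocal ties are broken by score,
#' then lexicographic subject id, so verdicts are deterministic and
#' independent of input order.
#'
#' @param reference_proteins Named character vector or \code{AAStringSet}
#'   of reference protein sequences (non-empty).
#' @param transcriptome Named character vector or \code{DNAStringSet} of
#'   contigs (may be empty: the report then has zero candidates).
#' @param backend A search backend
#'   (\code{\link{builtin_search_backend}()} by default).
#' @param top_k Candidates retained per query (default 10).
#' @param min_score Minimum forward-search score for a candidate. Scores
#'   are backend-dependent; for the built-in backend this is a raw
#'   Smith-Waterman score and the default (50) is conservative for
#'   proteins of typical length. A free parameter: lower it to chase
#'   weaker family members, raise it to cut noise.
#' @param families Optional named character vector mapping each reference
#'   protein id to a family name; defaults to one family per protein.
#' @param relaxed When TRUE, a candidate is also verified if its
#'   reciprocal top hit belongs to the same declared family as the query
#'   (rather than being the query itself).
#' @return A list of class \code{family_recovery_report}:
#'   \code{candidates} (data.frame family / query / candidate / score /
#'   reciprocal_top / verified) and \code{families} (data.frame family /
#'   n_candidates / n_verified / recovered).
#' @export
recover_families <- function(reference_proteins, transcriptome,
                             backend = builtin_search_backend(),
                             top_k = 10L, min_score = 50,
                             families = NULL, relaxed = FALSE) {
  refs <- as.character(reference_proteins)
  names(refs) <- names(reference_proteins)
  if (length(refs) == 0L) stop("empty reference protein set")
  if (is.null(names(refs)) || anyDuplicated(names(refs))) {
    stop("reference proteins must carry unique names")
  }
  if (top_k < 1L) stop("top_k must be >= 1")
  tx <- as.character(transcriptome)
  names(tx) <- names(transcriptome)
  if (is.null(families)) {
    families <- stats::setNames(names(refs), names(refs))
  }
  empty_cand <- data.frame(
    family = character(), query = character(), candidate = character(),
    score = numeric(), reciprocal_top = character(), verified = logical(),
    stringsAsFactors = FALSE)

  if (length(tx) == 0L) {
    fam <- data.frame(family = unique(unname(families)),
                      n_candidates = 0L, n_verified = 0L, recovered = FALSE,
                      stringsAsFactors = FALSE)
    return(structure(list(candidates = empty_cand, families = fam),
                     class = "family_recovery_report"))
  }

  fwd <- backend(refs, tx, mode = "protein-vs-translated-nucleotide")
  cand_rows <- do.call(rbind, lapply(split(fwd, fwd$query_id), function(d) {
    d <- d[d$score >= min_score, , drop = FALSE]
    utils::head(d[order(-d$score, d$subject_id), , drop = FALSE], top_k)
  }))
  if (is.null(cand_rows) || nrow(cand_rows) == 0L) {
    fam <- data.frame(family = unique(unname(families)),
                      n_candidates = 0L, n_verified = 0L, recovered = FALSE,
                      stringsAsFactors = FALSE)
    return(structure(list(candidates = empty_cand, families = fam),
                     class = "family_recovery_report"))
  }

  cand_ids <- sort(unique(cand_rows$subject_id))
  rev <- backend(tx[cand_ids], refs, mode = "nucleotide-translated-vs-protein")
  top_rev <- vapply(cand_ids, function(cid) {
    d <- rev[rev$query_id == cid, , drop = FALSE]
    d$subject_id[order(-d$score, d$subject_id)][1L]
  }, character(1))

  cand <- data.frame(
    family = unname(families[cand_rows$query_id]),
    query = cand_rows$query_id,
    candidate = cand_rows$subject_id,
    score = cand_rows$score,
    reciprocal_top = unname(top_rev[cand_rows$subject_id]),
    stringsAsFactors = FALSE
  )
  cand$verified <- cand$reciprocal_top == cand$query
  if (relaxed) {
    cand$verified <- cand$verified |
      (families[cand$reciprocal_top] == cand$family)
  }
  cand <- cand[order(cand$family, cand$query, -cand$score, cand$candidate), ]
  rownames(cand) <- NULL

  all_fams <- unique(unname(families))
  fam <- do.call(rbind, lapply(all_fams, function(f) {
    d <- cand[cand$family == f, , drop = FALSE]
    data.frame(family = f, n_candidates = nrow(d),
               n_verified = sum(d$verified),
               recovered = any(d$verified), stringsAsFactors = FALSE)
  }))
  rownames(fam) <- NULL
  structure(list(candidates = cand, families = fam),
            class = "family_recovery_report")
}

#' @export
print.family_recovery_report <- function(x, ...) {
  cat("family_recovery_report:", nrow(x$candidates), "candidates across",
      nrow(x$families), "families;",
      sum(x$candidates$verified), "verified\n")
  print(x$families, row.names = FALSE)
  invisible(x)
}

#' Write a family recovery report as TSV
#' @param report A \code{\link{recover_families}} result.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_family_report <- function(report, path) {
  utils::write.table(report$candidates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
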