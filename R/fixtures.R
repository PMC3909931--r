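#' Generate a synthetic transcriptome with known embedded ORFs
#'
#' Contigs of random nucleotide composition; a stated fraction carry an
#' embedded open reading frame (ATG, >= 30 random stop-free codons, stop)
#' at a random forward-frame offset, with the ORF coordinates recorded as
#' ground truth. Output is a pure function of \code{seed}.
#'
#' @param n_contigs Number of contigs (>= 1).
#' @param length_range Length-2 integer vector of min/max contig length
#'   (within [60, 20000] nt; >= 96 nt required when ORFs are requested,
#'   the minimum for start + 30 codons + stop).
#' @param orf_fraction Fraction of contigs carrying an embedded ORF.
#' @param seed Integer seed.
#' @return A list: \code{contigs} (named \code{DNAStringSet}) and
#'   \code{orf_truth} (data.frame contig_id / orf_start / orf_end /
#'   frame, 1-based closed coordinates on the forward strand).
#' @export
gen_transcriptome <- function(n_contigs, length_range = c(200L, 2000L),
                              orf_fraction = 0.5, seed = 1L) {
  if (n_contigs < 1L) stop("n_contigs must be >= 1")
  if (length_range[1L] < 60L || length_range[2L] > 20000L) {
    stop("length_range must lie within [60, 20000] nt")
  }
  min_orf <- 96L  # ATG + 30 codons + stop
  if (orf_fraction > 0 && length_range[1L] < min_orf) {
    stop("contigs shorter than ", min_orf,
         " nt cannot carry the minimum ORF; raise length_range")
  }
  bases <- c("A", "C", "G", "T")
  stops <- c("TAA", "TAG", "TGA")
  codons <- apply(expand.grid(bases, bases, bases), 1L, paste0, collapse = "")
  sense_codons <- setdiff(codons, stops)
  with_seed(seed, {
    lens <- sample(length_range[1L]:length_range[2L], n_contigs,
                   replace = TRUE)
    has_orf <- seq_len(n_contigs) <= round(orf_fraction * n_contigs)
    seqs <- character(n_contigs)
    truth <- list()
    for (i in seq_len(n_contigs)) {
      s <- paste(sample(bases, lens[i], replace = TRUE), collapse = "")
      if (has_orf[i]) {
        max_codons <- (lens[i] - 6L) %/% 3L - 1L
        n_cod <- sample(30L:min(max_codons, 120L), 1L)
        orf <- paste0("ATG",
                      paste(sample(sense_codons, n_cod, replace = TRUE),
                            collapse = ""),
                      sample(stops, 1L))
        orf_len <- nchar(orf)
        start <- sample.int(lens[i] - orf_len + 1L, 1L)
        substr(s, start, start + orf_len - 1L) <- orf
        truth[[length(truth) + 1L]] <- data.frame(
          contig_id = sprintf("ctg%04d", i),
          orf_start = start, orf_end = start + orf_len - 1L,
          frame = ((start - 1L) %% 3L) + 1L,
          stringsAsFactors = FALSE)
      }
      seqs[i] <- s
    }
    contigs <- Biostrings::DNAStringSet(seqs)
    names(contigs) <- sprintf("ctg%04d", seq_len(n_contigs))
    orf_truth <- if (length(truth)) {
      do.call(rbind, c(truth, list(make.row.names = FALSE)))
    } else {
      data.frame(contig_id = character(), orf_start = integer(),
                 orf_end = integer(), frame = integer(),
                 stringsAsFactors = FALSE)
    }
    list(contigs = contigs, orf_truth = orf_truth)
  })
}

#' Generate synthetic read-to-contig alignment records
#'
#' Emulates a short-read alignment of fixed-length reads: each aligned
#' record lands on a contig with probability proportional to contig
#' length (longer transcripts attract proportionally more reads under
#' uniform sampling); a stated fraction of records is emitted unaligned
#' (FLAG 4). True per-contig aligned counts are returned alongside and
#' sum to exactly \code{round(n_reads * (1 - unaligned_fraction))}.
#'
#' @param contigs Named \code{DNAStringSet}.
#' @param n_reads Total number of records to emit.
#' @param read_length Read length in nt (must not exceed the shortest
#'   contig).
#' @param unaligned_fraction Fraction of records emitted unaligned.
#' @param seed Integer seed.
#' @return A list: \code{alignments} (data.frame read_id / flag /
#'   reference_id / pos) and \code{counts} (named integer vector of true
#'   aligned counts per contig).
#' @export
gen_reads <- function(contigs, n_reads, read_length = 40L,
                      unaligned_fraction = 0.1, seed = 1L) {
  lens <- contig_lengths(contigs)
  ids <- names(contigs)
  if (read_length > min(lens)) {
    stop("read_length ", read_length, " exceeds the shortest contig (",
         min(lens), " nt)")
  }
  n_unaligned <- round(n_reads * unaligned_fraction)
  n_aligned <- n_reads - n_unaligned
  with_seed(seed, {
    ref <- if (n_aligned > 0L) {
      sample(ids, n_aligned, replace = TRUE, prob = lens)
    } else character()
    pos <- if (n_aligned > 0L) {
      vapply(ref, function(r) {
        sample.int(lens[match(r, ids)] - read_length + 1L, 1L)
      }, integer(1), USE.NAMES = FALSE)
    } else integer()
    aln <- data.frame(
      read_id = sprintf("read%06d", seq_len(n_reads)),
      flag = c(rep(0L, n_aligned), rep(4L, n_unaligned)),
      reference_id = c(ref, rep(NA_character_, n_unaligned)),
      pos = c(pos, rep(0L, n_unaligned)),
      stringsAsFactors = FALSE
    )
    # interleave aligned/unaligned records so file order carries no signal
    aln <- aln[sample.int(n_reads), , drop = FALSE]
    aln$read_id <- sprintf("read%06d", seq_len(n_reads))
    rownames(aln) <- NULL
    counts <- as.integer(table(factor(ref, levels = ids)))
    names(counts) <- ids
    list(alignments = aln, counts = counts)
  })
}

#' Write alignment records as a minimal SAM file
#'
#' Header plus the 11 mandatory fields; SEQ/QUAL are omitted (\code{*}),
#' CIGAR is a single match run. This is deliberately non-aligner-grade
#' SAM: just enough structure for per-contig read counting.
#'
#' @param alignments data.frame with \code{read_id}, \code{flag},
#'   \code{reference_id} (NA = unaligned) and optionally \code{pos}.
#' @param contigs Named \code{DNAStringSet} (for \code{@SQ} header lines).
#' @param path Output path.
#' @param read_length Read length used for the CIGAR run.
#' @return \code{path}, invisibly.
#' @export
write_sam <- function(alignments, contigs, path, read_length = 40L) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(contigs),
                      contig_lengths(contigs)))
  unaligned <- is.na(alignments$reference_id)
  pos <- if ("pos" %in% names(alignments)) alignments$pos else
    ifelse(unaligned, 0L, 1L)
  records <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
    alignments$read_id,
    alignments$flag,
    ifelse(unaligned, "*", alignments$reference_id),
    pos,
    ifelse(unaligned, 0L, 255L),
    ifelse(unaligned, "*", paste0(read_length, "M"))
  )
  writeLines(c(header, records), path)
  invisible(path)
}

#' Generate taxon-binned homology hit tables with known gene origins
#'
#' Each contig draws a true evolutionary stratum (an ancestor label of the
#' lineage model, or no hit) and receives hits in the bin realising that
#' stratum plus every bin closer to the focal species — the consistent
#' nested pattern a genuinely ancient gene leaves across taxonomically
#' restricted searches. Contaminants (at the stated rate) instead receive
#' hits only in the model's distal bins and none elsewhere, mimicking the
#' hit signature of a foreign organism. Out-of-lineage bins are used only
#' by the contamination channel.
#'
#' @param contigs Named \code{DNAStringSet} or character vector of contig
#'   ids.
#' @param model A \code{\link{lineage_model}}.
#' @param stratum_probs Named probability vector over the model's ancestor
#'   labels plus \code{"no_hit"}; must sum to 1 (tolerance 1e-9).
#' @param contamination_rate Per-contig probability of being emitted as a
#'   contaminant instead of drawing a stratum.
#' @param seed Integer seed.
#' @param hits_per_bin Range of hit rows per (contig, bin).
#' @return A list: \code{hits} (named list of per-bin hit data.frames in
#'   \code{\link{read_hits}} layout) and \code{truth} (data.frame
#'   contig_id / stratum (NA for contaminants and no-hit contigs) /
#'   contamination).
#' @export
gen_hit_tables <- function(contigs, model, stratum_probs,
                           contamination_rate = 0, seed = 1L,
                           hits_per_bin = c(1L, 3L)) {
  ids <- if (is.character(contigs)) contigs else names(contigs)
  labels <- model$ancestors
  allowed <- c(labels, "no_hit")
  if (!all(names(stratum_probs) %in% allowed)) {
    stop("stratum_probs names must be ancestor labels or 'no_hit'")
  }
  if (abs(sum(stratum_probs) - 1) > 1e-9) {
    stop("stratum_probs must sum to 1 (got ", sum(stratum_probs), ")")
  }
  distal <- model$distal_bins
  if (contamination_rate > 0 && length(distal) == 0L) {
    stop("model has no distal bins to host contaminant hits")
  }
  with_seed(seed, {
    contaminant <- stats::runif(length(ids)) < contamination_rate
    stratum <- rep(NA_character_, length(ids))
    n_clean <- sum(!contaminant)
    if (n_clean > 0L) {
      stratum[!contaminant] <- sample(names(stratum_probs), n_clean,
                                      replace = TRUE, prob = stratum_probs)
    }
    per_bin <- stats::setNames(
      vector("list", length(c(model$bins, model$out_of_lineage))),
      c(model$bins, model$out_of_lineage))
    add_hits <- function(bin, contig) {
      n <- sample(hits_per_bin[1L]:hits_per_bin[2L], 1L)
      data.frame(
        query_id = rep(contig, n),
        subject_id = sprintf("%s|prot%05d", gsub("[^A-Za-z]", "",
                                                 substr(bin, 1, 6)),
                             sample.int(99999L, n)),
        bin = bin,
        evalue = 10^-stats::runif(n, 4, 40),
        bitscore = round(stats::runif(n, 50, 500), 1),
        stringsAsFactors = FALSE)
    }
    rows <- list()
    for (i in seq_along(ids)) {
      bins_hit <- if (contaminant[i]) {
        distal
      } else if (is.na(stratum[i]) || stratum[i] == "no_hit") {
        character()
      } else {
        depth <- max(which(labels == stratum[i]))
        model$bins[seq_len(depth)]
      }
      for (b in bins_hit) rows[[length(rows) + 1L]] <- add_hits(b, ids[i])
    }
    all_hits <- if (length(rows)) {
      do.call(rbind, c(rows, list(make.row.names = FALSE)))
    } else {
      data.frame(query_id = character(), subject_id = character(),
                 bin = character(), evalue = numeric(),
                 bitscore = numeric(), stringsAsFactors = FALSE)
    }
    hits <- lapply(names(per_bin), function(b) {
      all_hits[all_hits$bin == b, , drop = FALSE]
    })
    names(hits) <- names(per_bin)
    truth <- data.frame(
      contig_id = ids,
      stratum = ifelse(stratum == "no_hit", NA_character_, stratum),
      contamination = contaminant,
      stringsAsFactors = FALSE)
    truth$no_hit <- !contaminant & (is.na(stratum) | stratum == "no_hit")
    list(hits = hits, truth = truth)
  })
}

#' Write one bin's hits in 12-column BLAST tabular layout
#'
#' Columns beyond query/subject/E-value/bitscore are filled with
#' placeholder alignment statistics.
#'
#' @param hits One element of \code{\link{gen_hit_tables}}'s \code{hits}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  n <- nrow(hits)
  if (n == 0L) { writeLines(character(), path); return(invisible(path)) }
  lines <- sprintf(
    "%s\t%s\t%.1f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%.1f",
    hits$query_id, hits$subject_id,
    90.0, 100L, 5L, 0L, 1L, 100L, 1L, 100L,
    formatC(hits$evalue, format = "e", digits = 2),
    hits$bitscore)
  writeLines(lines, path)
  invisible(path)
}

#' Generate a random multi-parent ontology in OBO 1.2 text
#'
#' Terms are numbered; each non-root term draws 1..max_parents parents
#' uniformly from strictly earlier terms, so the graph is acyclic by
#' construction. Term 1 is the single namespace root.
#'
#' @param n_terms Number of terms (>= 4).
#' @param max_parents Maximum parents per term (1 gives a tree).
#' @param seed Integer seed.
#' @param namespace Namespace string written on every term.
#' @return A list: \code{lines} (OBO text), \code{root_id},
#'   \code{term_ids}.
#' @export
gen_ontology <- function(n_terms, max_parents = 3L, seed = 1L,
                         namespace = "synthetic_process") {
  if (n_terms < 4L) stop("n_terms must be >= 4")
  ids <- sprintf("GO:%07d", seq_len(n_terms))
  with_seed(seed, {
    lines <- c("format-version: 1.2",
               paste0("default-namespace: ", namespace), "")
    for (i in seq_len(n_terms)) {
      lines <- c(lines, "[Term]",
                 paste0("id: ", ids[i]),
                 paste0("name: synthetic term ", i),
                 paste0("namespace: ", namespace))
      if (i > 1L) {
        k <- sample.int(min(max_parents, i - 1L), 1L)
        parents <- sort(sample.int(i - 1L, k))
        lines <- c(lines, paste0("is_a: ", ids[parents]))
      }
      lines <- c(lines, "")
    }
    list(lines = lines, root_id = ids[1L], term_ids = ids)
  })
}

#' Generate random GO annotations against an ontology
#'
#' @param dag An \code{ontology_dag}.
#' @param contig_ids Contig ids to annotate.
#' @param n_annotations Number of (contig, term) rows to draw.
#' @param seed Integer seed.
#' @param exclude_roots Do not annotate root terms (default TRUE).
#' @return data.frame \code{contig_id} / \code{label}.
#' @export
gen_annotations <- function(dag, contig_ids, n_annotations, seed = 1L,
                            exclude_roots = TRUE) {
  pool <- dag$terms$id[!dag$terms$obsolete]
  if (exclude_roots) pool <- setdiff(pool, go_roots(dag))
  with_seed(seed, data.frame(
    contig_id = sample(contig_ids, n_annotations, replace = TRUE),
    label = sample(pool, n_annotations, replace = TRUE),
    stringsAsFactors = FALSE))
}

# Reverse-translate a peptide with uniformly random synonymous codons.
reverse_translate <- function(peptide) {
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), unname(gc))
  paste(vapply(strsplit(peptide, "", fixed = TRUE)[[1L]], function(aa) {
    cands <- by_aa[[aa]]
    if (is.null(cands)) stop("cannot reverse-translate residue ", aa)
    cands[sample.int(length(cands), 1L)]
  }, character(1), USE.NAMES = FALSE), collapse = "")
}

# Mutate a peptide to a target identity by point substitution.
mutate_peptide <- function(peptide, identity, alphabet) {
  chars <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  n_sub <- round((1 - identity) * length(chars))
  if (n_sub > 0L) {
    pos <- sample.int(length(chars), n_sub)
    for (p in pos) {
      chars[p] <- sample(setdiff(alphabet, chars[p]), 1L)
    }
  }
  paste(chars, collapse = "")
}

#' Generate reference proteins, planted orthologs and decoy contigs
#'
#' Emulates a gene-family recovery experiment with known answers: random
#' reference proteins; for each, a planted ortholog created by point
#' substitutions down to the stated protein identity, reverse-translated
#' with uniformly random synonymous codons (identity is enforced at the
#' protein level, which is what a translated search sees), and embedded
#' in a contig at a random offset on a random strand; plus unrelated
#' random decoy contigs.
#'
#' @param n_families Number of gene families.
#' @param members_per_family Reference proteins per family.
#' @param ortholog_identity Protein identity of each planted ortholog to
#'   its reference (0 < identity <= 1; below 0.4 a warning is issued,
#'   recovery is no longer guaranteed).
#' @param n_decoys Number of unrelated decoy contigs.
#' @param seed Integer seed.
#' @param protein_length Range of reference protein lengths (aa).
#' @return A list: \code{proteins} (named character vector),
#'   \code{transcriptome} (named \code{DNAStringSet}), \code{pairs}
#'   (data.frame protein_id / contig_id / family),
#'   \code{families} (named vector protein_id -> family).
#' @export
gen_families <- function(n_families, members_per_family = 1L,
                         ortholog_identity = 0.8, n_decoys = 20L,
                         seed = 1L, protein_length = c(80L, 120L)) {
  if (ortholog_identity <= 0 || ortholog_identity > 1) {
    stop("ortholog_identity must be in (0, 1]")
  }
  if (ortholog_identity < 0.4) {
    warning("ortholog identity below 0.4: recovery is not guaranteed")
  }
  aa20 <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], NULL)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    proteins <- character(); fam_of <- character()
    pairs <- list(); contig_seqs <- character(); contig_ids <- character()
    idx <- 0L
    for (f in seq_len(n_families)) {
      fam <- sprintf("fam%02d", f)
      for (m in seq_len(members_per_family)) {
        idx <- idx + 1L
        pid <- sprintf("%s_p%02d", fam, m)
        plen <- sample(protein_length[1L]:protein_length[2L], 1L)
        prot <- paste(sample(aa20, plen, replace = TRUE), collapse = "")
        proteins[pid] <- prot
        fam_of[pid] <- fam
        ortho <- mutate_peptide(prot, ortholog_identity, aa20)
        cds <- reverse_translate(ortho)
        flank5 <- paste(sample(bases, sample(10:60, 1L), replace = TRUE),
                        collapse = "")
        flank3 <- paste(sample(bases, sample(10:60, 1L), replace = TRUE),
                        collapse = "")
        contig <- paste0(flank5, cds, flank3)
        if (stats::runif(1) < 0.5) {
          contig <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(contig)))
        }
        cid <- sprintf("ortho_%s", pid)
        contig_ids <- c(contig_ids, cid)
        contig_seqs <- c(contig_seqs, contig)
        pairs[[idx]] <- data.frame(protein_id = pid, contig_id = cid,
                                   family = fam, stringsAsFactors = FALSE)
      }
    }
    for (d in seq_len(n_decoys)) {
      contig_ids <- c(contig_ids, sprintf("decoy%03d", d))
      contig_seqs <- c(contig_seqs,
                       paste(sample(bases, sample(300:500, 1L),
                                    replace = TRUE), collapse = ""))
    }
    tx <- Biostrings::DNAStringSet(contig_seqs)
    names(tx) <- contig_ids
    list(proteins = proteins,
         transcriptome = tx,
         pairs = do.call(rbind, c(pairs, list(make.row.names = FALSE))),
         families = fam_of)
  })
}

#' Generate two species' EC annotation tables with a known partition
#'
#' @param n_shared,n_focal_only,n_reference_only Sizes of the three EC
#'   classes to plant.
#' @param contig_ids Focal-species contig ids to attach focal ECs to.
#' @param seed Integer seed.
#' @return A list: \code{focal} and \code{reference} annotation
#'   data.frames (contig_id / label) and \code{truth} (list of the three
#'   planted EC sets).
#' @export
gen_ec_tables <- function(n_shared, n_focal_only, n_reference_only,
                          contig_ids, seed = 1L) {
  n_total <- n_shared + n_focal_only + n_reference_only
  with_seed(seed, {
    ecs <- unique(sprintf("%d.%d.%d.%d",
                          sample.int(6L, n_total * 3L, replace = TRUE),
                          sample.int(20L, n_total * 3L, replace = TRUE),
                          sample.int(30L, n_total * 3L, replace = TRUE),
                          sample.int(200L, n_total * 3L, replace = TRUE)))
    if (length(ecs) < n_total) stop("EC pool exhausted; reduce class sizes")
    ecs <- ecs[seq_len(n_total)]
    shared <- ecs[seq_len(n_shared)]
    focal_only <- ecs[n_shared + seq_len(n_focal_only)]
    ref_only <- ecs[n_shared + n_focal_only + seq_len(n_reference_only)]
    focal_ecs <- c(shared, focal_only)
    focal <- data.frame(
      contig_id = sample(contig_ids, length(focal_ecs), replace = TRUE),
      label = focal_ecs, stringsAsFactors = FALSE)
    reference <- data.frame(
      contig_id = sprintf("refgene%04d", seq_along(c(shared, ref_only))),
      label = c(shared, ref_only), stringsAsFactors = FALSE)
    list(focal = focal, reference = reference,
         truth = list(shared = sort(shared),
                      only_focal = sort(focal_only),
                      only_reference = sort(ref_only)))
  })
}

#' Write a complete demo fixture bundle to a directory
#'
#' Generates and writes every input the toolkit consumes — contigs,
#' a SAM alignment, per-bin hit tables, an ontology, per-species GO and
#' EC annotation tables, reference proteins — plus a \code{truth/}
#' subdirectory of ground-truth tables. All content is a pure function of
#' \code{seed}; rerunning with the same seed reproduces every file
#' byte-identically.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed; per-component seeds are derived from
#'   it with \code{(seed, purpose-string)} hashing.
#' @param preset Size preset; \code{"demo"} is sized for interactive use
#'   (100 contigs, 5,000 reads).
#' @return Invisibly, a list of all generated objects plus \code{paths}.
#' @export
write_fixture_bundle <- function(out_dir, seed = 42L, preset = "demo") {
  if (!identical(preset, "demo")) stop("unknown preset: ", preset)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth_dir <- file.path(out_dir, "truth")
  dir.create(truth_dir, showWarnings = FALSE)

  model <- edwardsiid_lineage_model()
  # overall per-contig stratum probabilities: 60% of contigs produce no
  # hit; the 40% that do are spread over the strata with the deep
  # (pre-eukaryote) strata prominent, as is typical of animal
  # phylostratigraphy
  stratum_probs <- c(
    "no_hit" = 0.6,
    "Edwardsiidae ancestor" = 0.064,
    "Cnidaria ancestor" = 0.0088,
    "Eumetazoa ancestor" = 0.08,
    "Metazoa ancestor" = 0.0432,
    "Eukaryota ancestor" = 0.0672,
    "ancestor of Archaea + Eukaryota" = 0.06,
    "ancestor of Eubacteria + Eukaryota" = 0.0768)

  txg <- gen_transcriptome(100L, c(200L, 1000L), orf_fraction = 0.5,
                           seed = derive_seed(seed, "transcriptome"))
  rds <- gen_reads(txg$contigs, 5000L, read_length = 40L,
                   unaligned_fraction = 0.1,
                   seed = derive_seed(seed, "reads"))
  hitg <- gen_hit_tables(txg$contigs, model, stratum_probs,
                         contamination_rate = 0.05,
                         seed = derive_seed(seed, "hits"))
  ontg <- gen_ontology(60L, max_parents = 3L,
                       seed = derive_seed(seed, "ontology"))
  obo_path <- file.path(out_dir, "ontology.obo")
  writeLines(ontg$lines, obo_path)
  dag <- read_obo(obo_path)
  ann_a <- gen_annotations(dag, names(txg$contigs), 120L,
                           seed = derive_seed(seed, "annotations_focal"))
  ann_b <- gen_annotations(dag, sprintf("refgene%04d", 1:80), 100L,
                           seed = derive_seed(seed, "annotations_reference"))
  famg <- gen_families(3L, 1L, ortholog_identity = 0.8, n_decoys = 10L,
                       seed = derive_seed(seed, "families"))
  ecg <- gen_ec_tables(30L, 12L, 8L, names(txg$contigs),
                       seed = derive_seed(seed, "ec"))

  paths <- list(
    contigs = file.path(out_dir, "contigs.fa"),
    sam = file.path(out_dir, "alignments.sam"),
    obo = obo_path,
    model = file.path(out_dir, "lineage_model.tsv"),
    ann_focal = file.path(out_dir, "annotations_focal.tsv"),
    ann_reference = file.path(out_dir, "annotations_reference.tsv"),
    ec_focal = file.path(out_dir, "ec_focal.tsv"),
    ec_reference = file.path(out_dir, "ec_reference.tsv"),
    proteins = file.path(out_dir, "reference_proteins.fa"),
    family_tx = file.path(out_dir, "family_transcriptome.fa")
  )
  write_fasta(txg$contigs, paths$contigs)
  write_sam(rds$alignments, txg$contigs, paths$sam, read_length = 40L)
  write_lineage_model(model, paths$model)
  hit_dir <- file.path(out_dir, "hits")
  dir.create(hit_dir, showWarnings = FALSE)
  paths$hits <- stats::setNames(
    file.path(hit_dir, paste0(gsub("[^A-Za-z0-9]+", "_", names(hitg$hits)),
                              ".tsv")),
    names(hitg$hits))
  for (b in names(hitg$hits)) write_hit_table(hitg$hits[[b]], paths$hits[[b]])
  write_annotations(ann_a, paths$ann_focal)
  write_annotations(ann_b, paths$ann_reference)
  write_annotations(ecg$focal, paths$ec_focal)
  write_annotations(ecg$reference, paths$ec_reference)
  prot_set <- Biostrings::AAStringSet(famg$proteins)
  Biostrings::writeXStringSet(prot_set, paths$proteins)
  write_fasta(famg$transcriptome, paths$family_tx)

  utils::write.table(txg$orf_truth, file.path(truth_dir, "orfs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(contig_id = names(rds$counts), aligned_reads = rds$counts),
    file.path(truth_dir, "aligned_counts.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(hitg$truth, file.path(truth_dir, "strata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(famg$pairs, file.path(truth_dir, "ortholog_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(ec = unlist(ecg$truth, use.names = FALSE),
               class = rep(names(ecg$truth), lengths(ecg$truth))),
    file.path(truth_dir, "ec_classes.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(list(transcriptome = txg, reads = rds, hits = hitg,
                 ontology = ontg, annotations = list(a = ann_a, b = ann_b),
                 families = famg, ec = ecg, model = model, paths = paths))
}
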