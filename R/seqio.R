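#' Read a FASTA file of assembled contigs
#'
#' Reads a (possibly multi-line) FASTA file into a
#' \link[Biostrings]{DNAStringSet}. The contig id is the first
#' whitespace-delimited token of each header; sequences are uppercased on
#' read so downstream translation and alignment see a single case.
#'
#' @param path Path to a FASTA file.
#' @return A \code{DNAStringSet} named by contig id.
#' @details Duplicate ids and empty sequences are errors: both break the
#'   contract that a contig collection indexes uniquely by id.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1 first contig", "ACGT", "ACGT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate contig id(s) in FASTA: ", paste(dup, collapse = ", "))
  }
  if (any(Biostrings::width(x) == 0L)) {
    bad <- ids[Biostrings::width(x) == 0L]
    stop("empty sequence for contig(s): ", paste(bad, collapse = ", "))
  }
  out <- Biostrings::DNAStringSet(toupper(as.character(x)))
  names(out) <- ids
  out
}

#' Write contigs to FASTA
#'
#' @param contigs A named \code{DNAStringSet} (or named character vector).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(contigs, path) {
  if (is.character(contigs)) contigs <- Biostrings::DNAStringSet(contigs)
  Biostrings::writeXStringSet(contigs, path)
  invisible(path)
}

#' Read a tabular homology hit file for one taxonomic bin
#'
#' Reads a tab-separated hit table (default column layout: the standard
#' 12-column BLAST tabular format) and returns one record per retained hit,
#' tagged with the taxonomic bin it came from. Rows whose E-value exceeds
#' \code{evalue_max} are dropped; the drop count is attached as attribute
#' \code{"n_dropped"} and reported via \code{message()}.
#'
#' @param path Path to a tab-separated hit table without a header row.
#' @param bin Name of the taxonomic bin this table was searched against.
#' @param evalue_max Retain rows with E-value at or below this threshold.
#'   The default 1e-3 is the conventional permissive cutoff for annotation
#'   screens of this kind. Exposed because reasonable pipelines differ on
#'   whether the cutoff applies to raw or database-size-adjusted E-values.
#' @param col_map Named integer vector giving 1-based column positions of
#'   \code{query}, \code{subject}, \code{evalue} and \code{bitscore}.
#' @return A data.frame with columns \code{query_id}, \code{subject_id},
#'   \code{bin}, \code{evalue}, \code{bitscore}; attribute
#'   \code{"n_dropped"} holds the number of rows over threshold.
#' @export
read_hits <- function(path, bin,
                      evalue_max = 1e-3,
                      col_map = c(query = 1L, subject = 2L,
                                  evalue = 11L, bitscore = 12L)) {
  stopifnot(is.character(bin), length(bin) == 1L)
  need <- c("query", "subject", "evalue", "bitscore")
  if (!all(need %in% names(col_map))) {
    stop("col_map must name columns: ", paste(need, collapse = ", "))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    out <- data.frame(query_id = character(), subject_id = character(),
                      bin = character(), evalue = numeric(),
                      bitscore = numeric(), stringsAsFactors = FALSE)
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  maxcol <- max(col_map)
  short <- which(vapply(fields, length, integer(1)) < maxcol)
  if (length(short)) {
    stop("hit table row ", short[1L], " has fewer than ", maxcol, " columns")
  }
  pick <- function(i) vapply(fields, `[[`, character(1), i)
  ev_chr <- pick(col_map[["evalue"]])
  ev <- suppressWarnings(as.numeric(ev_chr))
  if (anyNA(ev)) {
    stop("non-numeric E-value at line ", which(is.na(ev))[1L],
         ": '", ev_chr[which(is.na(ev))[1L]], "'")
  }
  if (any(ev < 0)) stop("negative E-value at line ", which(ev < 0)[1L])
  bs <- suppressWarnings(as.numeric(pick(col_map[["bitscore"]])))
  if (anyNA(bs)) stop("non-numeric bit score at line ", which(is.na(bs))[1L])
  keep <- ev <= evalue_max
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message(n_dropped, " hit(s) dropped above E-value threshold ", evalue_max)
  }
  out <- data.frame(
    query_id = pick(col_map[["query"]])[keep],
    subject_id = pick(col_map[["subject"]])[keep],
    bin = bin,
    evalue = ev[keep],
    bitscore = bs[keep],
    stringsAsFactors = FALSE
  )
  if (nrow(out) == 0L) out$bin <- character(0)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Read a minimal SAM alignment file
#'
#' Parses only the fields the coverage analysis needs: QNAME, FLAG and
#' RNAME. Header lines (starting with \code{@}) are skipped. Records with
#' the unmapped bit (0x4) set are returned with \code{reference_id = NA}.
#' Secondary (0x100) and supplementary (0x800) records are excluded so that
#' one sequencing read contributes at most one record; the exclusion count
#' is attached as attribute \code{"n_excluded"}.
#'
#' @param path Path to a SAM file.
#' @return A data.frame with columns \code{read_id}, \code{flag} (integer),
#'   \code{reference_id} (NA for unaligned records).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  is_header <- startsWith(lines, "@")
  body_lineno <- which(!is_header & nzchar(lines))
  if (length(body_lineno) == 0L) {
    out <- data.frame(read_id = character(), flag = integer(),
                      reference_id = character(), stringsAsFactors = FALSE)
    attr(out, "n_excluded") <- 0L
    return(out)
  }
  fields <- strsplit(lines[body_lineno], "\t", fixed = TRUE)
  nf <- vapply(fields, length, integer(1))
  if (any(nf < 11L)) {
    bad <- which(nf < 11L)[1L]
    stop("SAM record at line ", body_lineno[bad], " has ", nf[bad],
         " fields (need >= 11)")
  }
  qname <- vapply(fields, `[[`, character(1), 1L)
  flag <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  if (anyNA(flag) || any(flag < 0L)) {
    bad <- which(is.na(flag) | flag < 0L)[1L]
    stop("invalid FLAG at line ", body_lineno[bad])
  }
  rname <- vapply(fields, `[[`, character(1), 3L)
  secondary <- bitwAnd(flag, 0x100L) != 0L
  supplementary <- bitwAnd(flag, 0x800L) != 0L
  drop <- secondary | supplementary
  n_excluded <- sum(drop)
  qname <- qname[!drop]; flag <- flag[!drop]; rname <- rname[!drop]
  unmapped <- bitwAnd(flag, 0x4L) != 0L
  rname[unmapped] <- NA_character_
  out <- data.frame(read_id = qname, flag = flag, reference_id = rname,
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Read an OBO 1.2 ontology into a DAG
#'
#' Parses \code{[Term]} stanzas (id, name, namespace, \code{is_a},
#' \code{is_obsolete}) into an ontology DAG object. Only \code{is_a} edges
#' are loaded by default; other relationship types can be admitted via
#' \code{relationships}. Obsolete terms are retained but flagged and carry
#' no edges. Acyclicity of the is_a graph is verified at load time.
#'
#' @param path Path to an OBO 1.2 file.
#' @param relationships Character vector of relationship types (from
#'   \code{relationship:} lines) to load as parent edges in addition to
#'   \code{is_a}. Default: none.
#' @return An object of class \code{ontology_dag}: a list with
#'   \itemize{
#'     \item \code{terms}: data.frame (id, name, namespace, obsolete)
#'     \item \code{parents}: named list, per term id, of parent term ids
#'     \item \code{children}: the reverse adjacency
#'   }
#' @export
read_obo <- function(path, relationships = character()) {
  lines <- readLines(path)
  lines <- sub("\\s*!.*$", "", lines)  # strip OBO trailing comments
  stanza_starts <- which(lines == "[Term]")
  default_ns <- NA_character_
  dn <- grep("^default-namespace:", lines, value = TRUE)
  if (length(dn)) default_ns <- trimws(sub("^default-namespace:", "", dn[1L]))

  ids <- character(); nms <- character(); nss <- character()
  obs <- logical(); parents <- list()
  boundaries <- c(stanza_starts, length(lines) + 1L)
  other_stanzas <- grep("^\\[(?!Term\\])", lines, perl = TRUE)
  for (s in seq_along(stanza_starts)) {
    from <- stanza_starts[s] + 1L
    to <- boundaries[s + 1L] - 1L
    nxt_other <- other_stanzas[other_stanzas >= from]
    if (length(nxt_other) && nxt_other[1L] <= to) to <- nxt_other[1L] - 1L
    block <- lines[seq.int(from, length.out = max(0L, to - from + 1L))]
    get1 <- function(key) {
      v <- grep(paste0("^", key, ":"), block, value = TRUE)
      if (length(v)) trimws(sub(paste0("^", key, ":"), "", v[1L])) else NA_character_
    }
    id <- get1("id")
    if (is.na(id) || !nzchar(id)) stop("[Term] stanza without an id (stanza ", s, ")")
    isa <- trimws(sub("^is_a:", "", grep("^is_a:", block, value = TRUE)))
    if (length(relationships)) {
      rel <- trimws(sub("^relationship:", "",
                        grep("^relationship:", block, value = TRUE)))
      for (r in rel) {
        tok <- strsplit(r, "\\s+")[[1L]]
        if (length(tok) >= 2L && tok[1L] %in% relationships) {
          isa <- c(isa, tok[2L])
        }
      }
    }
    ns <- get1("namespace")
    if (is.na(ns)) ns <- default_ns
    ids <- c(ids, id)
    nms <- c(nms, get1("name"))
    nss <- c(nss, ns)
    obs <- c(obs, identical(get1("is_obsolete"), "true"))
    parents[[id]] <- unique(isa)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate term id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  # obsolete terms carry no edges
  parents[ids[obs]] <- list(character(0))
  dangling <- setdiff(unique(unlist(parents)), ids)
  if (length(dangling)) {
    stop("is_a edge(s) reference unknown term id(s): ",
         paste(dangling, collapse = ", "))
  }
  edges <- data.frame(
    child = rep(ids, lengths(parents[ids])),
    parent = unlist(parents[ids], use.names = FALSE),
    stringsAsFactors = FALSE
  )
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                       vertices = data.frame(name = ids))
    if (!igraph::is_dag(g)) {
      cyc <- igraph::feedback_arc_set(g)
      e1 <- igraph::ends(g, cyc[[1L]])
      stop("cycle detected in is_a graph involving edge ",
           e1[1L], " -> ", e1[2L])
    }
  }
  children <- split(edges$child, factor(edges$parent, levels = ids))
  names(children) <- ids
  structure(
    list(
      terms = data.frame(id = ids, name = nms, namespace = nss,
                         obsolete = obs, stringsAsFactors = FALSE),
      parents = parents[ids],
      children = lapply(children, as.character)
    ),
    class = "ontology_dag"
  )
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat("ontology_dag:", nrow(x$terms), "terms (",
      sum(x$terms$obsolete), "obsolete ),",
      sum(lengths(x$parents)), "is_a edges\n")
  ns <- unique(stats::na.omit(x$terms$namespace))
  if (length(ns)) cat("namespaces:", paste(ns, collapse = ", "), "\n")
  invisible(x)
}

#' Read a two-column annotation table
#'
#' Reads a TSV with header \code{contig_id<TAB>label} mapping contigs to GO
#' term ids or EC numbers.
#'
#' @param path Path to the TSV.
#' @param dag Optional \code{ontology_dag}; when given, labels that do not
#'   resolve in the ontology are reported via a warning and attached as
#'   attribute \code{"unresolved"}.
#' @return data.frame with columns \code{contig_id}, \code{label}.
#' @export
read_annotations <- function(path, dag = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("annotation table needs columns contig_id, label")
  out <- data.frame(contig_id = df[[1L]], label = df[[2L]],
                    stringsAsFactors = FALSE)
  if (!is.null(dag)) {
    unresolved <- setdiff(unique(out$label), dag$terms$id)
    if (length(unresolved)) {
      warning(length(unresolved), " annotation label(s) do not resolve in ",
              "the ontology: ", paste(utils::head(unresolved, 5), collapse = ", "))
    }
    attr(out, "unresolved") <- unresolved
  }
  out
}

#' Write a two-column annotation table
#' @param ann data.frame with columns \code{contig_id}, \code{label}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_annotations <- function(ann, path) {
  utils::write.table(ann[, c("contig_id", "label")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
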