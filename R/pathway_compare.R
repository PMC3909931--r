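#' Normalise an Enzyme Commission number string
#'
#' Strips an optional \code{EC:}/\code{ec:} prefix and pads the identifier
#' to four dot-separated fields with \code{-} (so \code{"1.2.3"} becomes
#' \code{"1.2.3.-"}). Comparisons downstream are exact-string on the
#' normalised form; no hierarchical matching of partial ECs to their
#' children is attempted.
#'
#' @param ec Character vector of EC strings.
#' @return Normalised EC strings.
#' @export
normalize_ec <- function(ec) {
  x <- sub("^[Ee][Cc]:", "", trimws(ec))
  ok <- grepl("^[0-9]+(\\.([0-9]+|-)){0,3}$", x)
  if (any(!ok)) {
    stop("malformed EC number(s): ",
         paste(utils::head(x[!ok], 5), collapse = ", "))
  }
  vapply(x, function(e) {
    fields <- strsplit(e, ".", fixed = TRUE)[[1L]]
    paste(c(fields, rep("-", 4L - length(fields))), collapse = ".")
  }, character(1), USE.NAMES = FALSE)
}

#' Extract the EC-number set from an annotation table
#'
#' @param annotations data.frame (\code{contig_id}, \code{label}) of EC
#'   annotations, e.g. from \code{\link{read_annotations}}.
#' @return A list: \code{ec_set} (unique normalised EC strings) and
#'   \code{by_contig} (named list mapping each contig to its EC set).
#'   Malformed EC labels raise an error naming the offending row.
#' @export
extract_ec <- function(annotations) {
  if (nrow(annotations) == 0L) {
    return(list(ec_set = character(), by_contig = list()))
  }
  norm <- tryCatch(normalize_ec(annotations$label), error = function(e) {
    bad <- which(!grepl("^([Ee][Cc]:)?[0-9]+(\\.([0-9]+|-)){0,3}$",
                        trimws(annotations$label)))
    stop("malformed EC at row ", bad[1L], ": '",
         annotations$label[bad[1L]], "'", call. = FALSE)
  })
  by_contig <- lapply(split(norm, annotations$contig_id), unique)
  list(ec_set = sort(unique(norm)), by_contig = by_contig)
}

#' Partition two species' EC-number sets
#'
#' Splits the union of the focal and reference EC sets into shared,
#' focal-only and reference-only classes. \code{n_matched} is the number
#' of ECs found in the focal species, i.e. |shared| + |only_focal|.
#'
#' @param focal_set,reference_set Character vectors of normalised EC
#'   strings (\code{\link{normalize_ec}} is applied defensively).
#' @return A list of class \code{ec_partition}: \code{shared},
#'   \code{only_focal}, \code{only_reference} (sorted character vectors)
#'   and \code{n_matched}.
#' @examples
#' p <- compare_ec(c("1.1.1.1", "2.2.2.2"), c("2.2.2.2", "3.3.3.3"))
#' p$shared        # "2.2.2.2"
#' p$n_matched     # 2
#' @export
compare_ec <- function(focal_set, reference_set) {
  f <- unique(normalize_ec(focal_set))
  r <- unique(normalize_ec(reference_set))
  structure(list(
    shared = sort(intersect(f, r)),
    only_focal = sort(setdiff(f, r)),
    only_reference = sort(setdiff(r, f)),
    n_matched = length(f)
  ), class = "ec_partition")
}

#' @export
print.ec_partition <- function(x, ...) {
  cat("ec_partition:", x$n_matched, "ECs in focal species (",
      length(x$shared), "shared +", length(x$only_focal), "focal-only );",
      length(x$only_reference), "reference-only\n")
  invisible(x)
}

#' Default iPath class palette
#'
#' Shared enzymes draw green, reference-only red, focal-only yellow —
#' the conventional colouring for two-species pathway overlap maps.
#' @return Named character vector of hex colours.
#' @export
ipath_default_palette <- function() {
  c(shared = "#00ff00", only_reference = "#ff0000", only_focal = "#ffff00")
}

#' Emit an iPath selection edge list for an EC partition
#'
#' One line per EC number in the partition, in the iPath selection
#' dialect: \code{<EC> <#RRGGBB> W<width>}. ECs absent from both species
#' are simply not listed (the viewer renders unselected edges in its
#' default gray/black).
#'
#' @param partition An \code{\link{compare_ec}} result.
#' @param palette Named character vector mapping the classes
#'   \code{shared}, \code{only_focal}, \code{only_reference} to hex
#'   colours.
#' @param width Line width token (default 10).
#' @return Character vector of selection lines.
#' @export
ipath_edgelist <- function(partition, palette = ipath_default_palette(),
                           width = 10L) {
  need <- c("shared", "only_focal", "only_reference")
  missing <- setdiff(need, names(palette))
  if (length(missing)) {
    stop("palette missing class(es): ", paste(missing, collapse = ", "))
  }
  lines <- character()
  for (cls in need) {
    ecs <- partition[[cls]]
    if (length(ecs)) {
      lines <- c(lines, paste(ecs, palette[[cls]], paste0("W", width)))
    }
  }
  lines
}

#' Parse iPath selection lines back to (EC, class) assignments
#'
#' Inverse of \code{\link{ipath_edgelist}} under the same palette.
#'
#' @param lines Character vector of selection lines.
#' @param palette Palette used to write the lines.
#' @return data.frame with columns \code{ec}, \code{class}, \code{width}.
#' @export
parse_ipath_edgelist <- function(lines, palette = ipath_default_palette()) {
  if (length(lines) == 0L) {
    return(data.frame(ec = character(), class = character(),
                      width = integer(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, " ", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 3L)
  if (length(bad)) stop("malformed selection line ", bad[1L])
  col <- vapply(parts, `[[`, character(1), 2L)
  cls <- names(palette)[match(col, unlist(palette))]
  if (anyNA(cls)) stop("colour not in palette: ", col[which(is.na(cls))[1L]])
  data.frame(
    ec = vapply(parts, `[[`, character(1), 1L),
    class = cls,
    width = as.integer(sub("^W", "", vapply(parts, `[[`, character(1), 3L))),
    stringsAsFactors = FALSE
  )
}

#' Write an EC partition as a TSV table
#' @param partition An \code{\link{compare_ec}} result.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_ec_partition <- function(partition, path) {
  df <- data.frame(
    ec = c(partition$shared, partition$only_focal, partition$only_reference),
    class = rep(c("shared", "only_focal", "only_reference"),
                c(length(partition$shared), length(partition$only_focal),
                  length(partition$only_reference))),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
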