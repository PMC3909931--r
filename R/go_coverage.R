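#' All descendants of an ontology term
#'
#' Every term reachable from \code{term_id} by following is_a edges in the
#' child direction (transitively), excluding obsolete terms and the term
#' itself. Multi-parent descendants are returned once.
#'
#' @param dag An \code{ontology_dag} from \code{\link{read_obo}}.
#' @param term_id A term id present in the dag.
#' @return Character vector of descendant term ids (unordered set).
#' @export
go_descendants <- function(dag, term_id) {
  if (!term_id %in% dag$terms$id) stop("unknown term: ", term_id)
  seen <- character()
  frontier <- dag$children[[term_id]]
  while (length(frontier)) {
    new <- setdiff(frontier, seen)
    seen <- c(seen, new)
    frontier <- unique(unlist(dag$children[new], use.names = FALSE))
  }
  obsolete <- dag$terms$id[dag$terms$obsolete]
  setdiff(seen, c(obsolete, term_id))
}

#' All ancestors of an ontology term
#'
#' @param dag An \code{ontology_dag}.
#' @param term_id A term id present in the dag.
#' @return Character vector of ancestor ids (the term itself excluded).
#' @export
go_ancestors <- function(dag, term_id) {
  if (!term_id %in% dag$terms$id) stop("unknown term: ", term_id)
  seen <- character()
  frontier <- dag$parents[[term_id]]
  while (length(frontier)) {
    new <- setdiff(frontier, seen)
    seen <- c(seen, new)
    frontier <- unique(unlist(dag$parents[new], use.names = FALSE))
  }
  setdiff(seen, term_id)
}

#' Root terms of an ontology (optionally per namespace)
#'
#' @param dag An \code{ontology_dag}.
#' @param namespace Optional namespace to filter on.
#' @return Character vector of ids of non-obsolete terms with no parents.
#' @export
go_roots <- function(dag, namespace = NULL) {
  ids <- dag$terms$id[!dag$terms$obsolete & lengths(dag$parents) == 0L]
  if (!is.null(namespace)) {
    ids <- ids[dag$terms$namespace[match(ids, dag$terms$id)] == namespace]
  }
  ids
}

#' Sub-hierarchy annotation coverage below a start term
#'
#' Measures how much of the ontology sub-hierarchy under \code{start_term}
#' each species' annotation set reaches. Two counting units are supported
#' because summaries of this kind are reported both ways:
#' \describe{
#'   \item{\code{"children"} (default)}{units = the direct children of the
#'     start term (the "subcategories"). A unit counts as recovered for a
#'     species iff the unit itself or any of its descendants carries at
#'     least one direct annotation.}
#'   \item{\code{"terms"}}{units = every term in the subtree below the
#'     start term. A unit is recovered iff it is directly annotated.}
#' }
#' Annotations to the start term itself belong to no child unit; their
#' count is reported in \code{n_at_start} per species. Obsolete terms are
#' excluded from units and never recover anything.
#'
#' @param dag An \code{ontology_dag}.
#' @param annotations Named list: one annotation data.frame
#'   (\code{contig_id}, \code{label}) per species.
#' @param start_term Term id whose sub-hierarchy is analysed.
#' @param mode \code{"children"} or \code{"terms"}.
#' @return A list of class \code{subtree_coverage}: \code{start_term},
#'   \code{mode}, \code{units} (character vector), \code{n_units_total},
#'   \code{recovered} (named list of logical vectors per species),
#'   \code{n_recovered} (named integer vector), \code{n_at_start}.
#' @export
subtree_coverage <- function(dag, annotations, start_term,
                             mode = c("children", "terms")) {
  mode <- match.arg(mode)
  if (!start_term %in% dag$terms$id) stop("unknown term: ", start_term)
  obsolete <- dag$terms$id[dag$terms$obsolete]
  if (mode == "children") {
    units <- setdiff(dag$children[[start_term]], obsolete)
  } else {
    units <- go_descendants(dag, start_term)
  }
  per_species <- lapply(annotations, function(ann) {
    terms_annotated <- unique(ann$label)
    if (mode == "children") {
      vapply(units, function(u) {
        u %in% terms_annotated ||
          any(go_descendants(dag, u) %in% terms_annotated)
      }, logical(1))
    } else {
      units %in% terms_annotated
    }
  })
  n_at_start <- vapply(annotations, function(ann) {
    sum(ann$label == start_term)
  }, integer(1))
  structure(list(
    start_term = start_term,
    mode = mode,
    units = units,
    n_units_total = length(units),
    recovered = per_species,
    n_recovered = vapply(per_species, sum, integer(1)),
    n_at_start = n_at_start
  ), class = "subtree_coverage")
}

#' Compare two species' coverage of every subcategory under a namespace root
#'
#' Runs \code{\link{subtree_coverage}} for each direct child of the
#' namespace root and classifies each subcategory by which species
#' recovered anything under it: \code{both}, \code{A_only}, \code{B_only}
#' or \code{neither}.
#'
#' @param dag An \code{ontology_dag}.
#' @param annotations_a,annotations_b Annotation data.frames
#'   (\code{contig_id}, \code{label}) for species A and B.
#' @param namespace Namespace whose root's children are compared; when the
#'   dag has a single root, that root is used regardless.
#' @param mode Counting mode, as in \code{\link{subtree_coverage}}.
#' @param species_names Length-2 character vector naming A and B in the
#'   output.
#' @return data.frame with one row per root child: \code{start_term},
#'   \code{name}, \code{n_units_total}, recovered counts per species, and
#'   \code{classification}.
#' @export
compare_species <- function(dag, annotations_a, annotations_b,
                            namespace = NULL, mode = "children",
                            species_names = c("A", "B")) {
  if (nrow(dag$terms) == 0L) stop("empty ontology")
  roots <- go_roots(dag, namespace)
  if (length(roots) == 0L) stop("no root term found",
                                if (!is.null(namespace))
                                  paste0(" for namespace ", namespace))
  starts <- unique(unlist(dag$children[roots], use.names = FALSE))
  starts <- setdiff(starts, dag$terms$id[dag$terms$obsolete])
  ann <- list(annotations_a, annotations_b)
  names(ann) <- species_names
  rows <- lapply(starts, function(st) {
    cov <- subtree_coverage(dag, ann, st, mode = mode)
    # a subcategory is recovered for a species when the root child itself
    # or anything below it carries a direct annotation (a leaf subcategory
    # has no child units but is still recoverable in its own right)
    sub <- c(st, go_descendants(dag, st))
    hit_any <- vapply(ann, function(a) any(sub %in% a$label), logical(1))
    cls <- if (hit_any[[1L]] && hit_any[[2L]]) "both"
      else if (hit_any[[1L]]) paste0(species_names[1L], "_only")
      else if (hit_any[[2L]]) paste0(species_names[2L], "_only")
      else "neither"
    df <- data.frame(start_term = st,
                     name = dag$terms$name[match(st, dag$terms$id)],
                     n_units_total = cov$n_units_total,
                     stringsAsFactors = FALSE)
    df[[paste0("n_recovered_", species_names[1L])]] <- cov$n_recovered[[1L]]
    df[[paste0("n_recovered_", species_names[2L])]] <- cov$n_recovered[[2L]]
    df$classification <- cls
    df
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
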