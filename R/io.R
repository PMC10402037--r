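#' Read and write pipeline files
#'
#' Plain-text interchange for every pipeline table. CSVs are
#' comma-separated, UTF-8, with a mandatory header row and empty fields for
#' missing values. The atlas uses Allen-structure-graph field names (`id`,
#' `acronym`, `name`, `parent_structure_id`); count and connectivity
#' matrices carry their row labels in the first column.
#'
#' @param x object to write; `path` file path.
#' @param path file path.
#' @name bondmap-io
NULL

#' @rdname bondmap-io
#' @export
write_design <- function(x, path) write.csv(x, path, row.names = FALSE)

#' @rdname bondmap-io
#' @export
read_design <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  x$behavior_included <- as.logical(x$behavior_included)
  x$ieg_included <- as.logical(x$ieg_included)
  rownames(x) <- x$animal_id
  class(x) <- c("bond_design", "data.frame")
  x
}

#' @rdname bondmap-io
#' @export
write_counts <- function(x, path) {
  df <- data.frame(animal_id = rownames(x), as.data.frame(x),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
}

#' @rdname bondmap-io
#' @export
read_counts <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname bondmap-io
#' @export
write_atlas <- function(x, path) {
  nodes <- lapply(seq_len(nrow(x)), function(i) list(
    id = x$id[i], acronym = x$acronym[i], name = x$name[i],
    parent_structure_id = if (is.na(x$parent_id[i])) NULL else x$parent_id[i]))
  jsonlite::write_json(nodes, path, auto_unbox = TRUE, null = "null")
}

#' @rdname bondmap-io
#' @export
read_atlas <- function(path) {
  nodes <- jsonlite::read_json(path)
  out <- data.frame(
    id = vapply(nodes, function(n) as.integer(n$id), 0L),
    acronym = vapply(nodes, function(n) n$acronym, ""),
    name = vapply(nodes, function(n) n$name, ""),
    parent_id = vapply(nodes, function(n)
      if (is.null(n$parent_structure_id)) NA_integer_
      else as.integer(n$parent_structure_id), 0L),
    stringsAsFactors = FALSE)
  class(out) <- c("bond_atlas", "data.frame")
  out
}

#' @rdname bondmap-io
#' @export
write_connectivity <- function(x, path) {
  df <- data.frame(origin = rownames(x), as.data.frame(x),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
}

#' @rdname bondmap-io
#' @export
read_connectivity <- function(path) {
  m <- read_counts(path)
  if (!identical(rownames(m), colnames(m)))
    stop("connectivity row and column labels differ")
  m
}

#' @rdname bondmap-io
#' @export
write_behavior <- function(x, path) {
  dy <- attr(x, "dyadic")
  write.csv(x, path, row.names = FALSE)
  invisible(dy)
}

#' @rdname bondmap-io
#' @export
read_behavior <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' Validate pipeline input files
#'
#' Schema and cross-file checks over the pipeline's input files: column
#' presence and types per file, nonnegative counts, pair structure of the
#' design, atlas tree validity (unique ids, one root, resolvable parents),
#' and consistency across files (count rows are design animals, count units
#' covered by the atlas, behavior rows are design animals, square
#' connectivity).
#'
#' @param paths named list with any of `design`, `counts`, `atlas`,
#'   `behavior`, `connectivity` — file paths; omitted entries are skipped.
#' @return `data.frame` of violations (`file`, `check`, `detail`); zero
#'   rows means everything checked out.
#' @export
validate_inputs <- function(paths) {
  v <- list()
  bad <- function(file, check, detail)
    v[[length(v) + 1L]] <<- data.frame(file = file, check = check,
                                       detail = detail,
                                       stringsAsFactors = FALSE)
  design <- counts <- atlas <- NULL
  if (!is.null(paths$design)) {
    design <- try(read_design(paths$design), silent = TRUE)
    if (inherits(design, "try-error")) {
      bad("design", "readable", as.character(design)); design <- NULL
    } else {
      need <- c("animal_id", "pair_id", "sex", "partner_type", "timepoint",
                "block", "behavior_included", "ieg_included")
      miss <- setdiff(need, names(design))
      if (length(miss))
        bad("design", "columns", paste("missing:", paste(miss, collapse = ", ")))
      else {
        sz <- table(design$pair_id)
        if (any(sz != 2))
          bad("design", "pair_size",
              paste("pairs without exactly 2 animals:",
                    paste(names(sz)[sz != 2], collapse = ", ")))
        if (!all(design$timepoint %in% 1:4))
          bad("design", "timepoint_range", "timepoints outside 1..4")
        if (!all(design$block %in% 1:6))
          bad("design", "block_range", "blocks outside 1..6")
      }
    }
  }
  if (!is.null(paths$counts)) {
    counts <- try(read_counts(paths$counts), silent = TRUE)
    if (inherits(counts, "try-error")) {
      bad("counts", "readable", as.character(counts)); counts <- NULL
    } else {
      if (!is.numeric(counts)) bad("counts", "numeric", "non-numeric entries")
      else if (any(counts < 0))
        bad("counts", "nonnegative",
            paste("negative entries at",
                  paste(head(which(counts < 0)), collapse = ", ")))
      if (!is.null(design)) {
        extra <- setdiff(rownames(counts), design$animal_id)
        if (length(extra))
          bad("counts", "animals_in_design",
              paste("unknown animal ids:", paste(head(extra), collapse = ", ")))
      }
    }
  }
  if (!is.null(paths$atlas)) {
    atlas <- try(read_atlas(paths$atlas), silent = TRUE)
    if (inherits(atlas, "try-error")) {
      bad("atlas", "readable", as.character(atlas)); atlas <- NULL
    } else {
      if (anyDuplicated(atlas$id)) bad("atlas", "unique_ids", "duplicate ids")
      nroot <- sum(is.na(atlas$parent_id))
      if (nroot != 1) bad("atlas", "single_root", paste(nroot, "roots"))
      orphan <- !is.na(atlas$parent_id) & !(atlas$parent_id %in% atlas$id)
      if (any(orphan))
        bad("atlas", "parents_exist",
            paste("unresolvable parent for:",
                  paste(atlas$acronym[orphan], collapse = ", ")))
      if (!is.null(counts)) {
        extra <- setdiff(colnames(counts), atlas$acronym)
        if (length(extra))
          bad("counts", "units_in_atlas",
              paste("units not in atlas:", paste(head(extra), collapse = ", ")))
      }
    }
  }
  if (!is.null(paths$behavior)) {
    beh <- try(read_behavior(paths$behavior), silent = TRUE)
    if (inherits(beh, "try-error")) bad("behavior", "readable", as.character(beh))
    else {
      if (!"animal_id" %in% names(beh))
        bad("behavior", "columns", "missing: animal_id")
      else if (!is.null(design)) {
        extra <- setdiff(beh$animal_id, design$animal_id)
        if (length(extra))
          bad("behavior", "animals_in_design",
              paste("unknown animal ids:", paste(head(extra), collapse = ", ")))
      }
    }
  }
  if (!is.null(paths$connectivity)) {
    conn <- try(read_connectivity(paths$connectivity), silent = TRUE)
    if (inherits(conn, "try-error"))
      bad("connectivity", "readable", as.character(conn))
    else if (any(conn < 0)) bad("connectivity", "nonnegative", "negative entries")
  }
  if (!length(v))
    return(data.frame(file = character(0), check = character(0),
                      detail = character(0)))
  do.call(rbind, v)
}
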