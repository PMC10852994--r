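#' Read and write scalar fields as delimited text grids
#'
#' A field is stored as a tab-delimited grid of numbers, one image row per
#' line, no header. Masks are written as 0/1 grids.
#'
#' @param field numeric (or logical) matrix.
#' @param file path.
#' @return `read_field()` returns a numeric matrix; writers return the
#'   path invisibly.
#' @export
write_field <- function(field, file) {
  write.table(matrix(as.numeric(field), nrow(field), ncol(field)),
              file = file, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname write_field
#' @export
read_field <- function(file) {
  as.matrix(read.table(file, sep = "\t", header = FALSE))
}

#' Read and write observation stacks as per-observation grid files
#'
#' An observation stack is stored as one delimited grid file per
#' observation; the files share a grid and are combined into the
#' `npix x n` stack layout used throughout the package.
#'
#' @param stack `npix x n` stack with a `grid` attribute.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return `write_stack()` returns the file paths invisibly;
#'   `read_stack()` returns a stack.
#' @export
write_stack <- function(stack, dir, prefix = "obs") {
  grid <- .stack_grid(stack)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(seq_len(ncol(stack)), function(i) {
    p <- file.path(dir, sprintf("%s_%04d.tsv", prefix, i))
    write_field(matrix(stack[, i], grid[1], grid[2]), p)
    p
  }, character(1))
  invisible(paths)
}

#' @rdname write_stack
#' @param files character vector of grid files, in observation order.
#' @export
read_stack <- function(files) {
  fields <- lapply(files, read_field)
  d <- dim(fields[[1]])
  for (f in fields) if (!all(dim(f) == d)) stop("grid files disagree in shape")
  .as_stack(vapply(fields, as.numeric, numeric(prod(d))), d)
}

#' Export a boundary partition as CSV
#'
#' One row per boundary point: edge endpoints (1-based lattice indices),
#' interpolation weight, continuous coordinates and the `phi` segment
#' label.
#'
#' @param segments a `conjcr_segments` object.
#' @param file path.
#' @export
write_boundary_csv <- function(segments, file) {
  stopifnot(inherits(segments, "conjcr_segments"))
  pts <- segments$points
  pts$phi <- NA_character_
  for (nm in names(segments$segments))
    pts$phi[segments$segments[[nm]]] <- nm
  write.table(pts, file, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write an inference result to disk
#'
#' Writes the three confidence-region masks as 0/1 grids plus a JSON
#' sidecar recording the quantile `a`, `alpha`, `B`, seed, multiplier
#' kind, query, and the per-segment boundary point counts.
#'
#' @param result a `conjcr_inference` object.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @export
write_inference <- function(result, dir, prefix = "crs") {
  stopifnot(inherits(result, "conjcr_inference"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_field(result$crs$upper, file.path(dir, paste0(prefix, "_upper.tsv")))
  write_field(result$crs$point_estimate,
              file.path(dir, paste0(prefix, "_point.tsv")))
  write_field(result$crs$lower, file.path(dir, paste0(prefix, "_lower.tsv")))
  side <- list(a = result$boot$quantile_a, alpha = result$boot$alpha,
               B = result$boot$B, seed = result$boot$seed,
               multiplier = result$boot$multiplier,
               query = list(combine = result$query$combine,
                            negate = result$query$negate),
               segment_points = lapply(result$segments$segments, length))
  jsonlite::write_json(side, file.path(dir, paste0(prefix, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a design matrix or contrast vector from CSV
#'
#' The design is a headerless numeric CSV with one row per observation;
#' the contrast a single row (or column) of `p` numbers.
#'
#' @param file path.
#' @return numeric matrix / vector.
#' @export
read_design <- function(file) {
  as.matrix(read.table(file, sep = ",", header = FALSE))
}

#' @rdname read_design
#' @export
read_contrast <- function(file) {
  as.numeric(as.matrix(read.table(file, sep = ",", header = FALSE)))
}
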