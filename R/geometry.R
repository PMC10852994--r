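#' Pointwise minimum of several scalar fields
#'
#' @param fields list of numeric matrices on a common grid.
#' @return a numeric matrix.
#' @export
min_field <- function(fields) {
  if (!is.list(fields) || length(fields) == 0L)
    stop("'fields' must be a non-empty list of matrices")
  d <- dim(fields[[1]])
  for (f in fields) if (!all(dim(f) == d)) stop("fields must share a grid")
  Reduce(pmin, fields)
}

#' Excursion mask of a field at level zero
#'
#' `inside <=> field >= 0` (exact zeros count as inside). Applied to a
#' standardised field this is the excursion set of the target function at
#' the level `c`; applied to the minimum of standardised fields it is the
#' estimated conjunction set.
#'
#' @param field numeric matrix.
#' @return a logical matrix.
#' @export
excursion_mask <- function(field) {
  .check_field(field)
  field >= 0
}

#' Extract the sub-pixel zero boundary of a field
#'
#' Scans every 4-neighbour lattice edge whose endpoint values straddle
#' zero (`>= 0` at `p`, `< 0` at `q`) and emits the linearly interpolated
#' crossing `p + w (q - p)` with `w = f(p) / (f(p) - f(q))`. A pixel with
#' value exactly 0 next to a negative neighbour yields `w = 0` at the
#' pixel. Diagonal edges are not scanned, so every crossing lies on a
#' single lattice edge and interpolation stays one-dimensional
#' (marching-squares edge logic).
#'
#' @param field numeric matrix (finite values).
#' @return a data frame with one row per crossing: integer endpoint
#'   indices `pr, pc` (inside) and `qr, qc` (outside), the weight `w`,
#'   and continuous (1-based) coordinates `row, col`. May have zero rows.
#' @export
extract_zero_boundary <- function(field) {
  .check_field(field)
  nr <- nrow(field); nc <- ncol(field)
  res <- vector("list", 4L)
  # horizontal edges: (r, c) -- (r, c + 1)
  a <- field[, -nc, drop = FALSE]; b <- field[, -1L, drop = FALSE]
  idx <- which(a >= 0 & b < 0, arr.ind = TRUE)
  res[[1]] <- cbind(pr = idx[, 1], pc = idx[, 2], qr = idx[, 1], qc = idx[, 2] + 1L)
  idx <- which(b >= 0 & a < 0, arr.ind = TRUE)
  res[[2]] <- cbind(pr = idx[, 1], pc = idx[, 2] + 1L, qr = idx[, 1], qc = idx[, 2])
  # vertical edges: (r, c) -- (r + 1, c)
  a <- field[-nr, , drop = FALSE]; b <- field[-1L, , drop = FALSE]
  idx <- which(a >= 0 & b < 0, arr.ind = TRUE)
  res[[3]] <- cbind(pr = idx[, 1], pc = idx[, 2], qr = idx[, 1] + 1L, qc = idx[, 2])
  idx <- which(b >= 0 & a < 0, arr.ind = TRUE)
  res[[4]] <- cbind(pr = idx[, 1] + 1L, pc = idx[, 2], qr = idx[, 1], qc = idx[, 2])
  e <- do.call(rbind, res)
  fp <- field[cbind(e[, "pr"], e[, "pc"])]
  fq <- field[cbind(e[, "qr"], e[, "qc"])]
  w <- ifelse(fp == fq, 0, fp / (fp - fq))  # fp >= 0 > fq, so fp != fq in fact
  out <- data.frame(pr = e[, "pr"], pc = e[, "pc"],
                    qr = e[, "qr"], qc = e[, "qc"], w = w)
  out$row <- out$pr + w * (out$qr - out$pr)
  out$col <- out$pc + w * (out$qc - out$pc)
  out
}

#' Interpolate a field at boundary points
#'
#' Linear interpolation along each point's lattice edge:
#' `(1 - w) f(p) + w f(q)`. Interpolating the field the boundary was
#' extracted from returns (numerical) zeros.
#'
#' @param field numeric matrix.
#' @param points boundary data frame from [extract_zero_boundary()].
#' @return numeric vector of interpolated values.
#' @export
interpolate_at_boundary <- function(field, points) {
  if (nrow(points) == 0L) return(numeric(0))
  fp <- field[cbind(points$pr, points$pc)]
  fq <- field[cbind(points$qr, points$qc)]
  (1 - points$w) * fp + points$w * fq
}

# linear pixel indices of both edge endpoints
.boundary_pixels <- function(points, nr) {
  list(p = (points$pc - 1L) * nr + points$pr,
       q = (points$qc - 1L) * nr + points$qr)
}

#' Partition the conjunction boundary into combinatorial segments
#'
#' Each boundary point of the minimum field is assigned the subset
#' `phi` of conditions whose interpolated standardised field attains the
#' minimum there, up to a tolerance `delta`:
#' `phi = { i : g_i <= min_j g_j + delta }`. The segments partition the
#' boundary: every point belongs to exactly one `phi`. `delta` defaults to
#' `tau_n` in [conjunction_inference()], shrinking at the CLT rate so that
#' genuinely shared boundaries are captured at finite `n` while distinct
#' boundaries separate asymptotically.
#'
#' @param points boundary of the minimum field ([extract_zero_boundary()]).
#' @param fields list of the `M` standardised fields the minimum was
#'   taken over.
#' @param delta non-negative assignment tolerance.
#' @return an object of class `conjcr_segments`: list with `points`,
#'   `segments` (named list mapping `phi` labels such as `"1,2"` to row
#'   indices of `points`), `values` (the `P x M` interpolated field
#'   matrix), `delta` and `M`.
#' @export
partition_boundary <- function(points, fields, delta) {
  if (delta < 0) stop("'delta' must be non-negative")
  M <- length(fields)
  P <- nrow(points)
  V <- vapply(fields, interpolate_at_boundary, numeric(P), points = points)
  V <- matrix(V, nrow = P, ncol = M)
  if (P == 0L) {
    seg <- list()
  } else {
    mins <- do.call(pmin, lapply(seq_len(M), function(i) V[, i]))
    attain <- V <= mins + delta
    labels <- apply(attain, 1L, function(z) paste(which(z), collapse = ","))
    seg <- split(seq_len(P), labels)
  }
  structure(list(points = points, segments = seg, values = V,
                 delta = delta, M = M),
            class = "conjcr_segments")
}

#' @export
print.conjcr_segments <- function(x, ...) {
  cat(sprintf("boundary partition: %d points, %d conditions, delta = %.4g\n",
              nrow(x$points), x$M, x$delta))
  for (nm in names(x$segments))
    cat(sprintf("  phi = {%s}: %d points\n", nm, length(x$segments[[nm]])))
  invisible(x)
}
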