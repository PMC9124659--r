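## Pluggable projector backends.
##
## A backend supplies the forward/adjoint pair behind forward_project()
## and back_project(), plus (optionally) exact row/column absolute-sum
## queries of |A|^p used by the diagonal preconditioner. Backends with
## non-negative system-matrix entries that lack `weight_sums` fall back to
## projecting a ones volume / back-projecting the mask (exact for p = 1).

.flara_backends <- new.env(parent = emptyenv())

#' Register a projector backend
#'
#' @param name backend identifier.
#' @param project function `(u, geom) -> (m, n_det, n_alpha) array`.
#' @param backproject function `(stack, geom) -> (m, n, z) array`, the exact
#'   adjoint of `project`.
#' @param weight_sums optional function `(geom, wexp, mask_stack) -> list(row=, col=)`
#'   returning the row sums of `|A|^wexp` as a projection-shaped array and the
#'   column sums of `|M A|^wexp` (mask applied row-wise) as a volume-shaped
#'   array. When `NULL`, a ones-projection fallback is used (exact at
#'   `wexp = 1` for backends with non-negative entries).
#' @export
backend_register <- function(name, project, backproject, weight_sums = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            is.function(project), is.function(backproject))
  assign(name, list(project = project, backproject = backproject,
                    weight_sums = weight_sums),
         envir = .flara_backends)
  invisible(name)
}

#' List registered projector backends
#' @export
backend_list <- function() sort(ls(.flara_backends))

backend_get <- function(name) {
  if (!exists(name, envir = .flara_backends, inherits = FALSE))
    stop("unknown projector backend '", name, "'; registered: ",
         paste(backend_list(), collapse = ", "))
  get(name, envir = .flara_backends, inherits = FALSE)
}

backend_weight_sums <- function(be, geom, wexp, mask_stack) {
  if (!is.null(be$weight_sums))
    return(be$weight_sums(geom, wexp, mask_stack))
  if (wexp != 1)
    warning("backend lacks weight_sums; ones-projection fallback is exact ",
            "only for preconditioning exponent alpha = 1")
  ones <- array(1, geom$vol_shape)
  list(row = be$project(ones, geom), col = be$backproject(mask_stack, geom))
}

register_joseph_backend <- function() {
  backend_register(
    "joseph",
    project = function(u, geom) {
      d <- geom$vol_shape
      array(fp_parallel(as.numeric(u), d[1], d[2], d[3],
                        geom$angles_deg * pi / 180, geom$det_shape[2], 1.0),
            c(geom$det_shape, length(geom$angles_deg)))
    },
    backproject = function(stack, geom) {
      d <- geom$vol_shape
      array(bp_parallel(as.numeric(stack), d[1], d[2], d[3],
                        geom$angles_deg * pi / 180, geom$det_shape[2], 1.0),
            d)
    },
    weight_sums = function(geom, wexp, mask_stack) {
      d <- geom$vol_shape
      ang <- geom$angles_deg * pi / 180
      row <- array(fp_parallel(rep(1, prod(d)), d[1], d[2], d[3],
                               ang, geom$det_shape[2], wexp),
                   c(geom$det_shape, length(ang)))
      col <- array(bp_parallel(as.numeric(mask_stack), d[1], d[2], d[3],
                               ang, geom$det_shape[2], wexp),
                   d)
      list(row = row, col = col)
    })
}
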