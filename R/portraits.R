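#' Expression portrait of one entity
#'
#' Reshapes an entity's meta-gene expression, minus a reference mean, onto
#' the SOM grid (row-major, 0-based unit order). The resulting grid of
#' differential meta-gene expression is the entity's expression portrait:
#' positive values mark meta-genes over-expressed relative to the
#' reference, negative ones under-expressed.
#'
#' @param model \code{SOMModel}.
#' @param metagene_values numeric vector over units (length
#'   \code{grid_rows * grid_cols}).
#' @param reference_mean numeric vector over units subtracted from
#'   \code{metagene_values}; default 0.
#' @param entity_tag identifier stored with the portrait.
#' @return A \code{Portrait}: matrix of shape (grid_rows, grid_cols) with
#'   attribute \code{entity_tag}.
#' @export
portrait_of <- function(model, metagene_values, reference_mean = 0,
                        entity_tag = "") {
  stopifnot(inherits(model, "SOMModel"))
  n_units <- model$grid_rows * model$grid_cols
  if (length(metagene_values) != n_units)
    stop("metagene_values must have length ", n_units)
  if (!length(reference_mean) %in% c(1, n_units))
    stop("reference_mean must be scalar or length ", n_units)
  v <- metagene_values - reference_mean
  p <- matrix(v, nrow = model$grid_rows, ncol = model$grid_cols, byrow = TRUE)
  structure(p, entity_tag = entity_tag, class = c("Portrait", "matrix"))
}

#' Portraits of all meta-cells
#'
#' One portrait per meta-cell from the trained SOM weights, referenced to
#' the mean meta-gene expression over all meta-cells. These are the default
#' input to spot-module extraction.
#'
#' @param model \code{SOMModel}.
#' @return list of \code{Portrait} objects, one per meta-cell.
#' @export
metacell_portraits <- function(model) {
  stopifnot(inherits(model, "SOMModel"))
  ref <- rowMeans(model$weights)
  lapply(seq_len(ncol(model$weights)), function(j)
    portrait_of(model, model$weights[, j], ref,
                entity_tag = colnames(model$weights)[j] %||% sprintf("mc%d", j)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean portrait of a group of entities
#'
#' @param model \code{SOMModel}.
#' @param portraits non-empty list of \code{Portrait} objects of uniform
#'   shape.
#' @param entity_tag identifier of the group.
#' @return element-wise mean \code{Portrait}.
#' @export
group_portrait <- function(model, portraits, entity_tag = "group") {
  if (!length(portraits)) stop("portrait list must be non-empty")
  shapes <- vapply(portraits, function(p) paste(dim(p), collapse = "x"),
                   character(1))
  if (length(unique(shapes)) != 1) stop("portraits must have uniform shape")
  acc <- Reduce(`+`, lapply(portraits, unclass)) / length(portraits)
  structure(acc, entity_tag = entity_tag, class = c("Portrait", "matrix"))
}

#' Render a portrait to PNG
#'
#' Symmetric diverging blue-green-red scale: limits are
#' \code{c(-L, L)} with \code{L = max(|values|)}, so zero always maps to
#' the middle (green) color; over-expression is red, under-expression blue.
#' Rendering is pure: the same portrait yields a byte-identical file.
#'
#' @param portrait \code{Portrait}.
#' @param out_path output PNG path; one pixel per grid unit.
#' @param pixel_size integer up-scaling factor per unit (default 1).
#' @return Invisibly, \code{out_path}.
#' @export
render_portrait <- function(portrait, out_path, pixel_size = 1) {
  v <- unclass(portrait)
  if (any(!is.finite(v))) stop("portrait contains non-finite values")
  lim <- max(abs(v))
  z <- if (lim > 0) (v / lim + 1) / 2 else matrix(0.5, nrow(v), ncol(v))
  ramp <- grDevices::colorRamp(c("#0000FF", "#00FF00", "#FF0000"))
  rgb <- ramp(as.vector(z)) / 255
  img <- array(0, dim = c(nrow(v), ncol(v), 3))
  for (ch in 1:3) img[, , ch] <- matrix(rgb[, ch], nrow(v), ncol(v))
  if (pixel_size > 1) {
    img <- img[rep(seq_len(nrow(v)), each = pixel_size),
               rep(seq_len(ncol(v)), each = pixel_size), , drop = FALSE]
  }
  ok <- tryCatch({ png::writePNG(img, out_path); TRUE },
                 error = function(e)
                   stop("failed to write portrait to '", out_path, "': ",
                        conditionMessage(e)))
  invisible(out_path)
}

#' Export a portrait's values as a TSV grid
#'
#' @param portrait \code{Portrait}.
#' @param out_path TSV path.
#' @return Invisibly, \code{out_path}.
#' @export
write_portrait <- function(portrait, out_path) {
  utils::write.table(unclass(portrait), out_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(out_path)
}
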