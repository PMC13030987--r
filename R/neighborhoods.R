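#' Quartile-by-presence neighborhood classification
#'
#' Bins every in-mask cube into quartiles of the reference-class count
#' (type-7 quantile edges at Q1, Q2, Q3; a count equal to an edge goes to
#' the lower bin) and crosses the bin with the presence (count > 0) of two
#' other classes, yielding the fixed set of 16 composition categories.
#'
#' @param grid A `cube_grid`.
#' @param reference_class Class whose density defines the quartile bins.
#' @param presence_classes Character pair of classes scored present/absent.
#' @return A tibble (class `neighborhood_table`) with one row per in-mask
#'   cube: cube indices and coordinates, `ref_count`, `quartile_bin`
#'   (1-4), one logical `has_<class>` column per presence class, and
#'   `category` (factor with all 16 levels). Attributes: `reference_class`,
#'   `presence_classes`, `quartiles`.
#' @export
quartile_neighborhoods <- function(grid, reference_class, presence_classes) {
  if (length(presence_classes) != 2L) {
    stop_spatcube("`presence_classes` must name exactly two classes")
  }
  inm <- grid$cubes$in_mask
  ref <- cube_counts(grid, reference_class)[inm]
  q <- stats::quantile(ref, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  bin <- 1L + (ref > q[1]) + (ref > q[2]) + (ref > q[3])
  p1 <- cube_counts(grid, presence_classes[1])[inm] > 0
  p2 <- cube_counts(grid, presence_classes[2])[inm] > 0

  lev <- as.character(outer(
    outer(paste0("Q", 1:4), c("-", "+"), function(a, b) paste0(a, "_", presence_classes[1], b)),
    c("-", "+"),
    function(a, b) paste0(a, "_", presence_classes[2], b)
  ))
  cat_chr <- paste0(
    "Q", bin, "_",
    presence_classes[1], ifelse(p1, "+", "-"), "_",
    presence_classes[2], ifelse(p2, "+", "-")
  )
  out <- grid$cubes[inm, c("ix", "iy", "iz", "u_um", "v_um", "z_um")]
  out$ref_count <- ref
  out$quartile_bin <- as.integer(bin)
  out[[paste0("has_", presence_classes[1])]] <- p1
  out[[paste0("has_", presence_classes[2])]] <- p2
  out$category <- factor(cat_chr, levels = lev)
  attr(out, "reference_class") <- reference_class
  attr(out, "presence_classes") <- presence_classes
  attr(out, "quartiles") <- q
  class(out) <- c("neighborhood_table", class(out))
  out
}

#' Category histogram of a neighborhood table
#'
#' @param neighborhoods A `neighborhood_table`.
#' @return A tibble with all 16 `category` levels and their cube counts
#'   (categories with no cubes appear with n = 0).
#' @export
category_counts <- function(neighborhoods) {
  tb <- table(neighborhoods$category)
  tibble(category = names(tb), n = as.integer(tb))
}
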