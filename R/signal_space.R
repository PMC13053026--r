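#' The six referents of the game
#'
#' Fruit and vegetable referents communicated in the game, in canonical order.
#' Every target, guess, and ledger in the package is keyed by these labels.
#'
#' @return Character vector of length six.
#' @export
#' @examples
#' referents()
referents <- function() {
  c("banana", "eggplant", "strawberry", "blueberry", "orange", "kiwi")
}

#' Experimental conditions
#'
#' The three between-dyad conditions. `"high"`: both roles see colors.
#' `"low"`: both roles see the sender's pad position as a dot.
#' `"one_sided"`: the sender sees colors but the receiver sees a dot.
#'
#' @return Character vector of condition labels.
#' @export
conditions <- function() c("high", "low", "one_sided")

assert_pad <- function(u, v) {
  if (length(u) != length(v)) stop("u and v must have equal length")
  if (anyNA(u) || anyNA(v)) stop("pad coordinates must not be NA")
  if (any(u < 0 | u > 1) || any(v < 0 | v > 1)) {
    stop("pad coordinates must lie in [0, 1]; v = 0 is the bottom edge")
  }
  invisible(TRUE)
}

#' Map trackpad coordinates to CIELAB
#'
#' The signaling medium of the color conditions: a normalized finger position
#' `(u, v)` on the trackpad (`u = 0` left edge, `v = 0` bottom edge) is mapped
#' to a CIELAB color. The chroma axes are affine in the pad coordinates,
#' `a* = -128 + (1 - u) * 256` and `b* = -128 + (1 - v) * 256`, so the bottom
#' left corner is red and hue sweeps green/blue toward the opposite edges.
#' Lightness is 75 on the bottom half of the pad and falls linearly,
#' `L* = 120 - 90 * v`, above the vertical midpoint, reaching 30 at the top
#' edge; the two branches agree at `v = 0.5`, so the map is continuous.
#'
#' @param u,v Numeric vectors in `[0, 1]`; recycled against each other must be
#'   equal length.
#' @return A numeric matrix with one row per point and columns `L`, `a`, `b`.
#' @seealso [lab_to_rgb()], [render_view()]
#' @export
#' @examples
#' pad_to_lab(0, 0)      # red corner: L = 75, a = 128, b = 128
#' pad_to_lab(0.5, 0.5)  # neutral center: L = 75, a = 0, b = 0
pad_to_lab <- function(u, v) {
  assert_pad(u, v)
  a <- -128 + (1 - u) * 256
  b <- -128 + (1 - v) * 256
  L <- ifelse(v <= 0.5, 75, 120 - 90 * v)
  cbind(L = L, a = a, b = b)
}

#' Convert CIELAB colors to display sRGB
#'
#' Standard D65 CIELAB to sRGB conversion with per-channel clamping to
#' `[0, 1]`. Much of the pad colorspace is deliberately out of the sRGB gamut
#' (chroma runs to +/-128); clamping reproduces what a display shows for
#' those requests.
#'
#' @param lab Numeric matrix (or single length-3 vector) with columns
#'   `L`, `a`, `b`.
#' @return Matrix with columns `R`, `G`, `B` in `[0, 1]`.
#' @export
#' @examples
#' lab_to_rgb(c(100, 0, 0))  # white
#' lab_to_rgb(pad_to_lab(0, 0))  # clamps to pure red
lab_to_rgb <- function(lab) {
  if (is.null(dim(lab))) lab <- matrix(lab, nrow = 1)
  stopifnot(ncol(lab) == 3)
  if (any(lab[, 1] < 0 | lab[, 1] > 100)) stop("L must lie in [0, 100]")
  if (any(abs(lab[, 2:3]) > 128)) stop("a and b must lie in [-128, 128]")
  rgb <- grDevices::convertColor(lab, from = "Lab", to = "sRGB", clip = TRUE)
  rgb <- pmin(pmax(rgb, 0), 1)
  colnames(rgb) <- c("R", "G", "B")
  rgb
}

#' Does a given role see colors in a given condition?
#'
#' @param condition One of [conditions()].
#' @param role `"sender"` or `"receiver"`.
#' @return Logical scalar.
#' @export
sees_color <- function(condition, role) {
  condition <- match.arg(condition, conditions())
  role <- match.arg(role, c("sender", "receiver"))
  switch(condition,
    high = TRUE,
    low = FALSE,
    one_sided = (role == "sender")
  )
}

#' Render what a role sees for a sent pad point
#'
#' Resolves the condition-by-role signal table: in the high-iconicity
#' condition both roles see the color under the sender's finger; in the
#' low-iconicity condition both see a dot at the finger position; in the
#' one-sided condition the sender sees the color while the receiver sees the
#' dot. With no point sent (`u` NULL) the message panel is blank (its gray
#' default).
#'
#' @param condition One of [conditions()].
#' @param role `"sender"` or `"receiver"`.
#' @param u,v Scalar pad coordinates, or NULL for no signal.
#' @return A list with `kind` (`"color"`, `"dot"`, or `"blank"`) and
#'   `payload`: an `(L, a, b)` vector for colors, a `(u, v)` vector for dots,
#'   NULL for blank.
#' @export
#' @examples
#' render_view("one_sided", "receiver", 0.3, 0.7)  # dot at (0.3, 0.7)
#' render_view("high", "receiver", 0, 0)           # color (75, 128, 128)
render_view <- function(condition, role, u = NULL, v = NULL) {
  condition <- match.arg(condition, conditions())
  role <- match.arg(role, c("sender", "receiver"))
  if (is.null(u) || (length(u) == 1 && is.na(u))) {
    return(list(kind = "blank", payload = NULL))
  }
  assert_pad(u, v)
  if (sees_color(condition, role)) {
    list(kind = "color", payload = drop(pad_to_lab(u, v)[1, ]))
  } else {
    list(kind = "dot", payload = c(u = u, v = v))
  }
}

#' Sample the pad colorspace on a grid
#'
#' Convenience rasterization of the pad-to-color map for inspection or
#' export: an `n x n` grid over the unit square with the clamped sRGB
#' rendering at each cell.
#'
#' @param n Grid resolution per axis.
#' @return A tibble with columns `u`, `v`, `L`, `a`, `b`, `R`, `G`, `B`,
#'   and `hex`.
#' @export
colorspace_grid <- function(n = 64) {
  stopifnot(n >= 2)
  g <- seq(0, 1, length.out = n)
  uv <- expand.grid(u = g, v = g)
  lab <- pad_to_lab(uv$u, uv$v)
  rgb <- lab_to_rgb(lab)
  tibble::tibble(
    u = uv$u, v = uv$v,
    L = lab[, "L"], a = lab[, "a"], b = lab[, "b"],
    R = rgb[, "R"], G = rgb[, "G"], B = rgb[, "B"],
    hex = grDevices::rgb(rgb[, "R"], rgb[, "G"], rgb[, "B"])
  )
}
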