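#' Construct a rectangular microelectrode array layout
#'
#' Builds the electrode lattice geometry for a microelectrode array (MEA):
#' a `rows` x `cols` grid at a fixed inter-electrode pitch. Coordinates are
#' row-major, so electrode `e` sits at row `ceiling(e / cols)`, column
#' `((e - 1) %% cols) + 1`, with x increasing along columns and y along rows.
#'
#' @param rows,cols lattice dimensions (each at least 2).
#' @param pitch inter-electrode spacing in mm (0.4 mm for the Utah-style
#'   arrays this package targets).
#' @return an object of class `mm_layout`: list with `rows`, `cols`, `pitch`,
#'   `n` (electrode count) and `coords` (n x 2 matrix, mm).
#' @examples
#' lay <- make_layout(8, 8, 0.4)  # 3.2 mm x 3.2 mm array, span 2.8 mm
#' @export
make_layout <- function(rows, cols, pitch) {
  if (rows < 2 || cols < 2) stop("rows and cols must each be >= 2")
  if (pitch <= 0) stop("pitch must be positive")
  rc <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  coords <- cbind(x = (rc$col - 1) * pitch, y = (rc$row - 1) * pitch)
  structure(list(rows = rows, cols = cols, pitch = pitch,
                 n = rows * cols, coords = coords),
            class = "mm_layout")
}

#' @export
print.mm_layout <- function(x, ...) {
  cat(sprintf("mm_layout: %d x %d lattice, pitch %g mm, %d electrodes\n",
              x$rows, x$cols, x$pitch, x$n))
  invisible(x)
}

#' Drop the four corner electrodes of a lattice
#'
#' Emulates the 96-channel 4 mm x 4 mm array convention, where a 10 x 10
#' lattice is populated at 96 sites with the four corners absent.
#'
#' @param layout an `mm_layout`.
#' @return the layout with corner electrodes removed; `n` and `coords`
#'   shrink, and `retained` gives the surviving row-major indices.
#' @export
drop_corners <- function(layout) {
  stopifnot(inherits(layout, "mm_layout"))
  r <- layout$rows; c <- layout$cols
  corners <- c(1, c, (r - 1) * c + 1, r * c)
  keep <- setdiff(seq_len(layout$n), corners)
  layout$coords <- layout$coords[keep, , drop = FALSE]
  layout$n <- length(keep)
  layout$retained <- keep
  layout
}

# Internal: n x n logical adjacency of the 4-neighborhood (lattice nearest
# neighbors at exactly one pitch). Works for layouts with dropped sites.
mm_lattice_neighbors <- function(layout) {
  d <- as.matrix(stats::dist(layout$coords))
  abs(d - layout$pitch) < 1e-9
}

#' Plant spatially contiguous modules on a lattice
#'
#' Partitions the electrode lattice into `n_modules` rectangular blocks
#' (4-connected, hence spatially contiguous) whose diameter `2 * R_g`
#' approximates `target_diameter`. The block tiling is chosen to make the
#' blocks as square as possible; the mapping from blocks to module ids is
#' shuffled under `seed` so module labels carry no positional information.
#'
#' @param layout an `mm_layout`.
#' @param n_modules number of modules (at most the electrode count).
#' @param target_diameter desired module diameter `2 * R_g` in mm (default
#'   1.3 mm, the scale of interest for cortical micro-modules).
#' @param seed optional integer seed (label shuffling only).
#' @return an object of class `mm_modulemap`: list with `labels` (integer per
#'   electrode), `n_modules`, and the `layout`.
#' @export
plant_modules <- function(layout, n_modules, target_diameter = 1.3,
                          seed = NULL) {
  stopifnot(inherits(layout, "mm_layout"))
  if (n_modules < 1 || n_modules > layout$n)
    stop("n_modules must be between 1 and the electrode count")

  if (n_modules == 1) {
    map <- structure(list(labels = rep(1L, layout$n), n_modules = 1L,
                          layout = layout), class = "mm_modulemap")
    return(map)
  }

  # choose a tiling nr x nc = n_modules with near-square blocks
  divisors <- which(n_modules %% seq_len(n_modules) == 0)
  best <- NULL; best_cost <- Inf
  for (nr in divisors) {
    nc <- n_modules / nr
    if (nr > layout$rows || nc > layout$cols) next
    cost <- abs(layout$rows / nr - layout$cols / nc)
    if (cost < best_cost) { best_cost <- cost; best <- c(nr, nc) }
  }
  if (is.null(best)) stop("n_modules does not fit this lattice")
  nr <- best[1]; nc <- best[2]

  row_grp <- ceiling(seq_len(layout$rows) * nr / layout$rows)
  col_grp <- ceiling(seq_len(layout$cols) * nc / layout$cols)

  # electrode -> lattice (row, col) from coordinates (robust to dropped sites)
  rr <- round(layout$coords[, 2] / layout$pitch) + 1
  cc <- round(layout$coords[, 1] / layout$pitch) + 1
  block <- (row_grp[rr] - 1L) * nc + col_grp[cc]

  perm <- mm_with_seed(seed, sample.int(n_modules))
  labels <- perm[block]

  map <- structure(list(labels = as.integer(labels),
                        n_modules = as.integer(n_modules), layout = layout),
                   class = "mm_modulemap")

  diam <- module_diameter(map$labels, layout)
  feasible <- target_diameter > layout$pitch
  if (feasible && any(abs(diam - target_diameter) / target_diameter > 0.25))
    warning(sprintf(paste0("planted module diameters (%.2f-%.2f mm) deviate ",
                           "more than 25%% from target %.2f mm; using best ",
                           "feasible tiling"),
                    min(diam), max(diam), target_diameter))
  map
}

#' @export
print.mm_modulemap <- function(x, ...) {
  cat(sprintf("mm_modulemap: %d modules over %d electrodes (sizes: %s)\n",
              x$n_modules, length(x$labels),
              paste(tabulate(x$labels), collapse = ", ")))
  invisible(x)
}
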