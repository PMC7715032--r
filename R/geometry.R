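#' Default sheet geometry for the unfolded hippocampal coordinate frame
#'
#' Positions live on an unfolded two-dimensional sheet per subfield. The
#' longitudinal (septotemporal) axis runs from 0 mm at the temporal pole to
#' the septal pole; the transverse (proximodistal) axis runs from 0 at the
#' proximal border (for CA3, the boundary with the dentate gyrus) and
#' increases distally. The sheet dimensions are configuration with
#' anatomically motivated defaults; the literature does not pin them down
#' numerically, so they are documented assumptions (see the methods
#' vignette).
#'
#' @param ec_long,ec_trans,dg_long,dg_trans,ca3_long,ca3_trans subfield
#'   extents in mm along the longitudinal and transverse axes.
#' @return A named list of per-subfield extents (mm), class
#'   `"ca3net_geometry"`.
#' @export
default_geometry <- function(ec_long = 10, ec_trans = 4,
                             dg_long = 10, dg_trans = 1.5,
                             ca3_long = 10, ca3_trans = 2) {
  ext <- list(
    EC  = c(longitudinal = ec_long,  transverse = ec_trans),
    DG  = c(longitudinal = dg_long,  transverse = dg_trans),
    CA3 = c(longitudinal = ca3_long, transverse = ca3_trans)
  )
  for (s in names(ext)) {
    if (any(ext[[s]] <= 0)) {
      stop("extents must be positive (subfield ", s, ")", call. = FALSE)
    }
  }
  structure(ext, class = "ca3net_geometry")
}

#' Place neuron populations on the unfolded sheet
#'
#' Creates a population layout: per-neuron identities and unfolded 2D
#' positions for the entorhinal cortex (EC), dentate gyrus (DG) and CA3.
#' Neurons are placed uniformly at random over each subfield's extent
#' unless a density profile is supplied. Dentate granule cells are labelled
#' as suprapyramidal or infrapyramidal blade with a configurable fraction.
#' The reference full-scale configuration contains 112,000 EC cells,
#' 120,000 granule cells and 25,000 CA3 pyramidal cells.
#'
#' @param n_ec,n_dg,n_ca3 population sizes (non-negative integers).
#' @param geometry sheet extents from [default_geometry()].
#' @param seed integer RNG seed; the layout is reproducible bit-for-bit for
#'   a fixed seed.
#' @param supra_fraction fraction of granule cells assigned to the
#'   suprapyramidal blade (default 0.5).
#' @param density optional named list of functions
#'   `function(longitudinal, transverse)` returning a relative (not
#'   necessarily normalized) density used for rejection sampling; names in
#'   `c("EC", "DG", "CA3")`.
#' @return An object of class `"ca3net_layout"`: a data.frame with columns
#'   `population`, `id` (dense 0..N-1 per population), `longitudinal`,
#'   `transverse` (mm) and `blade` (`"suprapyramidal"`/`"infrapyramidal"`
#'   for DG, `"none"` otherwise), plus attributes `geometry` and `seed`.
#' @examples
#' lay <- build_layout(100, 100, 50, seed = 1)
#' table(lay$population)
#' @export
build_layout <- function(n_ec, n_dg, n_ca3, geometry = default_geometry(),
                         seed = 1L, supra_fraction = 0.5, density = NULL) {
  sizes <- c(EC = n_ec, DG = n_dg, CA3 = n_ca3)
  if (any(is.na(sizes)) || any(sizes < 0)) {
    stop("population sizes must be non-negative", call. = FALSE)
  }
  if (!inherits(geometry, "ca3net_geometry")) {
    stop("`geometry` must come from default_geometry()", call. = FALSE)
  }
  storage.mode(sizes) <- "integer"
  rng <- local_rng(seed)
  parts <- lapply(names(sizes), function(pop) {
    n <- sizes[[pop]]
    ext <- geometry[[pop]]
    if (n == 0L) {
      return(data.frame(population = character(0), id = integer(0),
                        longitudinal = numeric(0), transverse = numeric(0),
                        blade = character(0), stringsAsFactors = FALSE))
    }
    pos <- sample_sheet(n, ext, density[[pop]])
    blade <- rep("none", n)
    if (pop == "DG") {
      blade <- ifelse(stats::runif(n) < supra_fraction,
                      "suprapyramidal", "infrapyramidal")
    }
    data.frame(population = rep(pop, n), id = seq_len(n) - 1L,
               longitudinal = pos$longitudinal, transverse = pos$transverse,
               blade = blade, stringsAsFactors = FALSE)
  })
  rng()  # restore caller RNG state
  lay <- do.call(rbind, parts)
  rownames(lay) <- NULL
  structure(lay, geometry = geometry, seed = as.integer(seed),
            class = c("ca3net_layout", "data.frame"))
}

# Uniform (or rejection-sampled) placement over a rectangular sheet.
sample_sheet <- function(n, ext, dens = NULL) {
  if (is.null(dens)) {
    return(list(longitudinal = stats::runif(n, 0, ext[["longitudinal"]]),
                transverse   = stats::runif(n, 0, ext[["transverse"]])))
  }
  # rejection sampling against the sheet-wide maximum on a probe grid
  gl <- seq(0, ext[["longitudinal"]], length.out = 101)
  gt <- seq(0, ext[["transverse"]], length.out = 101)
  dmax <- max(outer(gl, gt, dens))
  if (!is.finite(dmax) || dmax <= 0) stop("density profile must be positive")
  out_l <- numeric(0); out_t <- numeric(0)
  while (length(out_l) < n) {
    m <- max(2L * (n - length(out_l)), 64L)
    pl <- stats::runif(m, 0, ext[["longitudinal"]])
    pt <- stats::runif(m, 0, ext[["transverse"]])
    keep <- stats::runif(m) * dmax < dens(pl, pt)
    out_l <- c(out_l, pl[keep]); out_t <- c(out_t, pt[keep])
  }
  list(longitudinal = out_l[seq_len(n)], transverse = out_t[seq_len(n)])
}

#' @export
print.ca3net_layout <- function(x, ...) {
  cat("<ca3net_layout> ", nrow(x), " neurons (",
      paste(sprintf("%s: %d", names(table(x$population)),
                    as.integer(table(x$population))), collapse = ", "),
      "), seed ", attr(x, "seed"), "\n", sep = "")
  invisible(x)
}

#' Subset the layout for one population
#' @param layout a `"ca3net_layout"`.
#' @param population one of `"EC"`, `"DG"`, `"CA3"`.
#' @return data.frame rows for that population, id-ordered.
#' @export
layout_population <- function(layout, population) {
  out <- layout[layout$population == population, , drop = FALSE]
  out[order(out$id), , drop = FALSE]
}

#' CA3 section grid (3 x 3 longitudinal/transverse sections)
#'
#' CA3 is partitioned along the transverse axis into CA3c (proximal), CA3b
#' and CA3a (distal) -- equal thirds by default -- and covered along the
#' longitudinal axis by three overlapping 5-mm windows centered at 7.5 mm
#' (septal), 5.0 mm (middle) and 2.5 mm (temporal), each extending 2.5 mm
#' above and below its center.
#'
#' @param transverse_extent CA3 transverse extent (mm).
#' @param transverse_bounds optional increasing vector of the two interior
#'   CA3c/CA3b and CA3b/CA3a boundaries (mm); defaults to equal thirds.
#' @param long_centers longitudinal window centers (mm), septal first.
#' @param long_halfwidth half-width of each longitudinal window (mm).
#' @return An object of class `"ca3net_section_grid"`.
#' @export
section_grid <- function(transverse_extent = 2,
                         transverse_bounds = NULL,
                         long_centers = c(septal = 7.5, middle = 5.0,
                                          temporal = 2.5),
                         long_halfwidth = 2.5) {
  if (long_halfwidth <= 0) stop("half-width must be > 0", call. = FALSE)
  if (is.null(transverse_bounds)) {
    transverse_bounds <- transverse_extent * c(1, 2) / 3
  }
  if (length(transverse_bounds) != 2L || any(diff(transverse_bounds) <= 0)) {
    stop("need two increasing interior transverse boundaries", call. = FALSE)
  }
  structure(list(transverse_extent = transverse_extent,
                 transverse_bounds = transverse_bounds,
                 long_centers = long_centers,
                 long_halfwidth = long_halfwidth),
            class = "ca3net_section_grid")
}

#' Transverse column (CA3c/CA3b/CA3a) of a CA3 position
#'
#' Boundary ties go to the distal side: intervals are half-open
#' `[low, high)` with the lower edge inclusive, so a position exactly on
#' the CA3c/CA3b boundary belongs to CA3b.
#'
#' @param transverse transverse coordinate(s), mm.
#' @param grid a [section_grid()].
#' @return character vector in `c("CA3c", "CA3b", "CA3a")`.
#' @export
transverse_column <- function(transverse, grid = section_grid()) {
  b <- grid$transverse_bounds
  ifelse(transverse < b[1], "CA3c", ifelse(transverse < b[2], "CA3b", "CA3a"))
}

#' Assign a CA3 position to its 3 x 3 sections
#'
#' Returns every (longitudinal row, transverse column) section containing
#' the position. Longitudinal windows overlap, so a neuron can belong to
#' several rows (a position at 5.0 mm is inside all three default windows);
#' it belongs to exactly one transverse column. Window membership uses
#' half-open intervals `[center - hw, center + hw)`.
#'
#' @param longitudinal,transverse position (mm) of a CA3 neuron.
#' @param grid a [section_grid()].
#' @param subfield subfield label of the position; must be `"CA3"`.
#' @return data.frame with columns `row` (name of the longitudinal window),
#'   `column` (`"CA3c"`/`"CA3b"`/`"CA3a"`), one line per containing section.
#' @examples
#' assign_section(7.5, 0.1)              # (septal, CA3c)
#' nrow(assign_section(5, 1))            # all three rows
#' @export
assign_section <- function(longitudinal, transverse, grid = section_grid(),
                           subfield = "CA3") {
  if (!identical(subfield, "CA3")) {
    stop("sections are defined for CA3 positions only", call. = FALSE)
  }
  stopifnot(length(longitudinal) == 1L, length(transverse) == 1L)
  ctr <- grid$long_centers
  hw <- grid$long_halfwidth
  inside <- longitudinal >= (ctr - hw) & longitudinal < (ctr + hw)
  rows <- names(ctr)[inside]
  if (is.null(rows)) rows <- as.character(seq_along(ctr))[inside]
  data.frame(row = rows,
             column = rep(transverse_column(transverse, grid),
                          length(rows)),
             stringsAsFactors = FALSE)
}

#' Section membership matrix for all CA3 neurons in a layout
#'
#' @param layout a `"ca3net_layout"`.
#' @param grid a [section_grid()].
#' @return logical matrix (CA3 neurons x 9 sections), columns named
#'   `"<row>.<column>"`, rows ordered by CA3 id.
#' @export
section_membership <- function(layout, grid = section_grid()) {
  ca3 <- layout_population(layout, "CA3")
  ctr <- grid$long_centers
  hw <- grid$long_halfwidth
  col_of <- transverse_column(ca3$transverse, grid)
  cols <- c("CA3c", "CA3b", "CA3a")
  out <- matrix(FALSE, nrow(ca3), length(ctr) * 3L,
                dimnames = list(NULL, as.vector(outer(
                  names(ctr), cols, function(r, co) paste(r, co, sep = ".")))))
  for (r in seq_along(ctr)) {
    in_row <- ca3$longitudinal >= (ctr[r] - hw) &
      ca3$longitudinal < (ctr[r] + hw)
    for (co in cols) {
      out[, paste(names(ctr)[r], co, sep = ".")] <- in_row & col_of == co
    }
  }
  out
}

# Run code under a private RNG stream; returns a function restoring the
# caller's RNG state. Keeps layout/connectome generation reproducible
# without clobbering the session RNG.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    invisible(NULL)
  }
}
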