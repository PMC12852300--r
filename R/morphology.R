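#' Cell compartments
#'
#' A compartmented cell is described by fractional volumes
#' \eqn{f_i = V_i / V_{cell}} for the cytosol (`c`), mitochondria (`m`),
#' nucleus (`n`), vacuoles (`v`) and endoplasmic reticulum (`e`).  The
#' fractions must be strictly positive and sum to 1.
#'
#' @param fractions named numeric vector of fractional volumes; names must
#'   be a subset of `c("c", "m", "n", "v", "e")` and must include `"c"`.
#' @return a named numeric vector of class `bp_compartments`.
#' @export
compartments <- function(fractions) {
  if (is.null(names(fractions)) || any(!nzchar(names(fractions))))
    stop("compartment fractions must be named")
  bad <- setdiff(names(fractions), c("c", "m", "n", "v", "e"))
  if (length(bad)) stop("unknown compartment id(s): ", paste(bad, collapse = ", "))
  if (!"c" %in% names(fractions)) stop("a cytosol compartment 'c' is required")
  if (any(fractions <= 0) || any(fractions >= 1))
    stop("fractional volumes must satisfy 0 < f_i < 1")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("fractional volumes must sum to 1 (got ", format(sum(fractions)), ")")
  structure(fractions, class = "bp_compartments")
}

#' Cell morphology
#'
#' Collects the whole-cell volume, the exponential growth rate and the
#' compartment fractional volumes, plus the geometric parameters needed to
#' estimate membrane volumes: bilayer thickness, the ratio of mitochondrial
#' inner- to outer-membrane area, the number of nuclear membrane layers,
#' the fraction of the ER compartment occupied by membrane, and the volume
#' of one phospholipid molecule.
#'
#' @param V_cell cell volume in liters.
#' @param alpha_cell exponential growth rate in 1/min.
#' @param fractions named fractional volumes, see [compartments()].
#' @param bilayer_thickness_um membrane bilayer thickness in micrometers.
#' @param mito_inner_to_outer_area_ratio inner/outer mitochondrial membrane
#'   area ratio.
#' @param nuclear_membrane_layers number of bilayers around the nucleus.
#' @param er_membrane_fraction fraction of the ER compartment volume that is
#'   membrane.
#' @param pl_molecule_volume volume of a single phospholipid molecule in
#'   liters.
#' @param mito_cylinder_radius_um radius used to approximate the
#'   mitochondrial outer membrane as long thin cylinders, in micrometers.
#'   Only used when no explicit outer-membrane area is supplied to
#'   [membrane_volumes()].
#' @return an object of class `bp_morphology`.
#' @export
cell_morphology <- function(V_cell = 42e-15,
                            alpha_cell = 0.003333,
                            fractions = c(c = 0.643, m = 0.10, n = 0.03,
                                          v = 0.2005, e = 0.0265),
                            bilayer_thickness_um = 0.006,
                            mito_inner_to_outer_area_ratio = 3,
                            nuclear_membrane_layers = 2,
                            er_membrane_fraction = 0.5,
                            pl_molecule_volume = 3e-24,
                            mito_cylinder_radius_um = 0.3) {
  if (V_cell <= 0) stop("V_cell must be > 0")
  if (alpha_cell < 0) stop("alpha_cell must be >= 0")
  geom <- c(bilayer_thickness_um, mito_inner_to_outer_area_ratio,
            nuclear_membrane_layers, er_membrane_fraction,
            pl_molecule_volume, mito_cylinder_radius_um)
  if (any(geom <= 0)) stop("all geometry parameters must be > 0")
  structure(list(
    V_cell = V_cell,
    alpha_cell = alpha_cell,
    fractions = compartments(fractions),
    bilayer_thickness_um = bilayer_thickness_um,
    mito_inner_to_outer_area_ratio = mito_inner_to_outer_area_ratio,
    nuclear_membrane_layers = nuclear_membrane_layers,
    er_membrane_fraction = er_membrane_fraction,
    pl_molecule_volume = pl_molecule_volume,
    mito_cylinder_radius_um = mito_cylinder_radius_um
  ), class = "bp_morphology")
}

#' @export
print.bp_morphology <- function(x, ...) {
  cat("Cell morphology: V_cell =", format(x$V_cell), "L, alpha_cell =",
      format(x$alpha_cell), "/min\n")
  cat("  fractional volumes:",
      paste(sprintf("%s=%.4g", names(x$fractions), x$fractions),
            collapse = ", "), "\n")
  invisible(x)
}

# sphere surface area (um^2) from volume in liters; 1 L = 1e15 um^3
sphere_area_um2 <- function(V_liters) {
  V_um3 <- V_liters * 1e15
  r <- (3 * V_um3 / (4 * pi))^(1 / 3)
  4 * pi * r^2
}

#' Membrane volumes from cell morphology
#'
#' The plasma membrane, nuclear membrane and vacuolar membrane are treated
#' as spherical shells: surface area \eqn{4\pi r^2} with \eqn{r} from the
#' compartment volume, multiplied by the bilayer thickness.  The nuclear
#' area counts once per membrane layer (two for a double membrane).
#' Mitochondria are approximated as long thin cylinders of the radius
#' stored in the morphology (or an explicit outer-membrane area can be
#' supplied), and the inner membrane adds `mito_inner_to_outer_area_ratio`
#' times the outer membrane volume.  The ER membrane volume is a fixed
#' fraction of the ER compartment volume.
#'
#' @param morph a [cell_morphology()] object.
#' @param mito_outer_area_um2 optional explicit mitochondrial outer-membrane
#'   area in square micrometers; when `NULL` the cylinder approximation is
#'   used.
#' @return list with per-compartment membrane volumes (liters) and `total`.
#' @export
membrane_volumes <- function(morph, mito_outer_area_um2 = NULL) {
  f <- morph$fractions
  th <- morph$bilayer_thickness_um
  um3_to_L <- 1e-15
  vols <- list()
  vols$plasma <- sphere_area_um2(morph$V_cell) * th * um3_to_L
  if ("n" %in% names(f)) {
    vols$nucleus <- sphere_area_um2(f[["n"]] * morph$V_cell) * th *
      morph$nuclear_membrane_layers * um3_to_L
  }
  if ("v" %in% names(f)) {
    vols$vacuole <- sphere_area_um2(f[["v"]] * morph$V_cell) * th * um3_to_L
  }
  if ("m" %in% names(f)) {
    V_m_um3 <- f[["m"]] * morph$V_cell * 1e15
    if (is.null(mito_outer_area_um2)) {
      # cylinder of radius rho: V = pi rho^2 L, lateral area = 2 pi rho L,
      # so area = 2 V / rho (end caps neglected for long thin cylinders)
      mito_outer_area_um2 <- 2 * V_m_um3 / morph$mito_cylinder_radius_um
    }
    outer_vol <- mito_outer_area_um2 * th * um3_to_L
    vols$mito <- (1 + morph$mito_inner_to_outer_area_ratio) * outer_vol
  }
  if ("e" %in% names(f)) {
    vols$er <- morph$er_membrane_fraction * f[["e"]] * morph$V_cell
  }
  vols$total <- sum(unlist(vols))
  vols
}

#' Phospholipid molecules per cell
#'
#' Total membrane volume divided by the volume of one phospholipid
#' molecule.
#'
#' @param total_membrane_volume liters.
#' @param pl_molecule_volume liters per molecule.
#' @return molecules per cell.
#' @export
pl_count <- function(total_membrane_volume, pl_molecule_volume = 3e-24) {
  if (pl_molecule_volume <= 0) stop("pl_molecule_volume must be > 0")
  if (total_membrane_volume < 0) stop("membrane volume must be >= 0")
  total_membrane_volume / pl_molecule_volume
}

#' Avogadro's number (1/mol)
#' @export
AVOGADRO <- 6.02214076e23

#' Convert copies per cell to cellular concentration
#'
#' @param copies_per_cell molecule count.
#' @param volume cell volume in liters.
#' @return concentration in micromolar.
#' @export
copies_to_concentration <- function(copies_per_cell, volume) {
  if (volume <= 0) stop("volume must be > 0")
  copies_per_cell / (AVOGADRO * volume) * 1e6
}

#' Mean gene length
#'
#' Average base pairs per gene for a genome of `total_bp` base pairs and
#' `n_genes` genes.
#'
#' @param total_bp total genome base pairs.
#' @param n_genes number of genes.
#' @return base pairs per gene.
#' @export
mean_gene_length <- function(total_bp, n_genes) {
  if (n_genes <= 0) stop("n_genes must be > 0")
  total_bp / n_genes
}

#' Convert cellular to local concentration (and back)
#'
#' A component confined to a compartment occupying fraction `f_i` of the
#' cell volume has local concentration `cellular / f_i`.
#'
#' @param cellular cellular concentration (uM).
#' @param f_i compartment fractional volume, 0 < f_i <= 1.
#' @return local concentration (uM).
#' @export
local_concentration <- function(cellular, f_i) {
  if (any(f_i <= 0) || any(f_i > 1)) stop("f_i must satisfy 0 < f_i <= 1")
  cellular / f_i
}

#' @rdname local_concentration
#' @param local local concentration (uM).
#' @export
cellular_concentration <- function(local, f_i) {
  if (any(f_i <= 0) || any(f_i > 1)) stop("f_i must satisfy 0 < f_i <= 1")
  local * f_i
}
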