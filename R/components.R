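#' Iron-center profile of a component
#'
#' Molar coefficients (centers per molecule) for the six iron-center kinds
#' carried by model components: heme (`FH`), mononuclear nonheme iron
#' (`FO`), di-iron Fe-O-Fe (`FF`), and the [Fe2S2] (`F2`), [Fe3S4] (`F3`)
#' and [Fe4S4] (`F4`) iron-sulfur clusters.  Fractional counts are allowed
#' because group-level coefficients arise from weighted averages over
#' member proteins.
#'
#' @param FH,FO,FF,F2,F3,F4 centers per molecule, nonnegative reals.
#' @return named numeric vector of class `bp_iron_profile`.
#' @export
iron_profile <- function(FH = 0, FO = 0, FF = 0, F2 = 0, F3 = 0, F4 = 0) {
  p <- c(FH = FH, FO = FO, FF = FF, F2 = F2, F3 = F3, F4 = F4)
  if (any(!is.finite(p)) || any(p < 0))
    stop("iron-center counts must be finite and >= 0")
  structure(p, class = "bp_iron_profile")
}

# irons contributed by one center of each kind
IRONS_PER_CENTER <- c(FH = 1, FO = 1, FF = 2, F2 = 2, F3 = 3, F4 = 4)

#' Iron atoms per molecule
#'
#' Sum of the molar iron-center coefficients weighted by the number of
#' irons each center kind carries (FH 1, FO 1, FF 2, F2 2, F3 3, F4 4).
#'
#' @param profile an [iron_profile()] or a named numeric vector with the
#'   six center counts.
#' @return iron atoms per molecule.
#' @export
iron_per_molecule <- function(profile) {
  if (!inherits(profile, "bp_iron_profile"))
    profile <- do.call(iron_profile, as.list(profile))
  sum(unclass(profile) * IRONS_PER_CENTER[names(profile)])
}

#' Member contribution to a group iron-center coefficient
#'
#' A member protein carrying `member_count` centers of some kind, entering
#' its group with dimensionless weight `member_weight` (its respiring
#' concentration over the group's), contributes their product to the group
#' molar coefficient for that center kind.
#'
#' @param member_count centers per member molecule (>= 0).
#' @param member_weight dimensionless member weight (>= 0).
#' @return contribution to the group coefficient.
#' @export
member_center_contribution <- function(member_count, member_weight) {
  if (member_count < 0 || member_weight < 0)
    stop("member count and weight must be >= 0")
  member_count * member_weight
}

#' Total group iron-center coefficient
#'
#' @param contributions numeric vector of member contributions (>= 0).
#' @return their sum.
#' @export
group_center_total <- function(contributions) {
  if (length(contributions) && any(contributions < 0))
    stop("contributions must be >= 0")
  sum(contributions)
}

#' Group concentration and member weights
#'
#' The concentration of a protein group is the arithmetic mean of its
#' members' respiring concentrations; each member's weight is its
#' concentration divided by the group concentration, so that the weights
#' average to exactly 1.
#'
#' @param member_respiring_concentrations nonempty numeric vector (uM).
#' @return list with `concentration` (uM) and `weights`.
#' @export
group_concentration <- function(member_respiring_concentrations) {
  x <- member_respiring_concentrations
  if (!length(x)) stop("member list must be nonempty")
  if (any(x < 0)) stop("concentrations must be >= 0")
  conc <- mean(x)
  weights <- if (conc > 0) x / conc else rep(1, length(x))
  list(concentration = conc, weights = weights)
}

#' Respiring-condition concentration of a member protein
#'
#' Fermenting-condition concentrations of mitochondrial proteins are
#' multiplied by 3 or 9 to account for the larger mitochondrial fractional
#' volume and higher expression under respiration; other proteins keep
#' multiplier 1.
#'
#' @param fermenting_conc uM.
#' @param multiplier one of 1, 3 or 9.
#' @return uM.
#' @export
respiring_concentration <- function(fermenting_conc, multiplier = 1) {
  if (fermenting_conc < 0) stop("concentration must be >= 0")
  if (!multiplier %in% c(1, 3, 9))
    stop("multiplier must be one of 1, 3, 9")
  fermenting_conc * multiplier
}

#' Group amino-acid coefficient
#'
#' Weighted sum of member residue counts: the number of amino acids
#' consumed per group molecule synthesized.
#'
#' @param members list of `c(aa, weight)` pairs, or a two-column
#'   matrix/data.frame with residue counts and weights.
#' @return amino acids per group molecule.
#' @export
group_aa_coefficient <- function(members) {
  if (!length(members)) return(0)
  m <- do.call(rbind, lapply(members, function(x) as.numeric(x[1:2])))
  if (any(m < 0)) stop("residue counts and weights must be >= 0")
  sum(m[, 1] * m[, 2])
}

#' Carbon coefficient from an amino-acid coefficient
#'
#' @param aa_total amino acids per group molecule.
#' @param carbons_per_aa carbons per amino acid (default 5).
#' @return carbons per group molecule.
#' @export
carbon_coefficient_from_aa <- function(aa_total, carbons_per_aa = 5) {
  if (aa_total < 0 || carbons_per_aa < 0) stop("inputs must be >= 0")
  aa_total * carbons_per_aa
}

#' Stoichiometric coefficient of an iron-center donor
#'
#' When a metallation reaction builds `centers_built` centers on one
#' acceptor molecule from a donor carrying `donor_capacity` centers per
#' molecule, consuming `centers_per_built_unit` donor centers per built
#' center, mass balance fixes the donor's stoichiometric coefficient at
#' `centers_built * centers_per_built_unit / donor_capacity`.
#'
#' @param centers_built centers built per acceptor molecule.
#' @param donor_capacity centers per donor molecule (> 0).
#' @param centers_per_built_unit donor centers consumed per built center.
#' @return stoichiometric coefficient on the donor.
#' @export
metallation_coefficient <- function(centers_built, donor_capacity,
                                    centers_per_built_unit = 1) {
  if (donor_capacity <= 0) stop("donor capacity must be > 0")
  if (centers_built < 0 || centers_per_built_unit < 0)
    stop("center counts must be >= 0")
  centers_built * centers_per_built_unit / donor_capacity
}

#' Total cellular iron
#'
#' Sums cellular concentration times iron atoms per molecule over
#' components, optionally broken down by compartment or by component.
#' Grouped sums partition the scalar total exactly.
#'
#' @param concentrations named numeric vector of cellular concentrations
#'   (uM).
#' @param profiles named list of [iron_profile()]s (or vectors accepted by
#'   [iron_per_molecule()]), covering every component with a nonzero
#'   concentration.
#' @param group_by `"none"` for the scalar total, `"compartment"` or
#'   `"component"` for a breakdown.
#' @param compartments named character vector mapping component name to
#'   compartment id; required for `group_by = "compartment"`.
#' @return total iron in uM, or a named breakdown with attribute `total`.
#' @export
total_iron <- function(concentrations, profiles,
                       group_by = c("none", "compartment", "component"),
                       compartments = NULL) {
  group_by <- match.arg(group_by)
  nm <- names(concentrations)
  if (is.null(nm)) stop("concentrations must be named")
  fe <- vapply(nm, function(n) {
    p <- profiles[[n]]
    if (is.null(p)) {
      if (concentrations[[n]] != 0)
        stop("missing iron profile for component with nonzero concentration: ", n)
      return(0)
    }
    iron_per_molecule(p)
  }, numeric(1))
  contrib <- unname(concentrations) * fe
  names(contrib) <- nm
  if (group_by == "none") return(sum(contrib))
  if (group_by == "component") {
    out <- contrib
  } else {
    if (is.null(compartments)) stop("compartments map required")
    out <- tapply(contrib, compartments[nm], sum)
    out <- stats::setNames(as.numeric(out), names(out))
  }
  attr(out, "total") <- sum(contrib)
  out
}
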