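## Closed-form back-of-envelope models: cytoskeletal filament counts per
## cell and the RodA : bound-PBP2 stoichiometry under depletion. No rounding
## is applied internally.

#' Number of cytoskeletal filaments per cell from copy number
#'
#' Idealized filaments of length `filament_length` with monomer repeat
#' `repeat_length` and `protofilaments` strands contain
#' `(filament_length / repeat_length) * protofilaments` monomers each (40
#' with the defaults); the filament count is the cellular monomer count
#' divided by that.
#'
#' @param monomers_per_cell monomer copy number per cell (e.g. 2000 in poor,
#'   11000 in rich growth medium).
#' @param filament_length filament length (um).
#' @param repeat_length monomer repeat along a protofilament (um).
#' @param protofilaments protofilament strands per filament.
#' @return list with `monomers_per_filament` and `n_filaments`.
#' @export
filament_count <- function(monomers_per_cell, filament_length = 0.100,
                           repeat_length = 0.005, protofilaments = 2) {
  if (repeat_length <= 0) stop("repeat_length must be > 0")
  stopifnot(filament_length > 0, protofilaments >= 1, monomers_per_cell >= 0)
  mpf <- (filament_length / repeat_length) * protofilaments
  list(monomers_per_filament = mpf,
       n_filaments = monomers_per_cell / mpf)
}

#' RodA depletion: RodA to PBP2 ratio over time and per bound molecule
#'
#' In an overexpression strain the initial stoichiometry is
#' `wildtype_ratio / overexpression_fold`. Under CRISPRi repression RodA
#' decays by dilution towards a residual expression fraction `f`:
#' `ratio(t) = ratio0 * ((1 - f) * 2^(-t / t_d) + f)`. Dividing a measured
#' (or modeled) ratio by the bound fraction gives RodA per bound molecule.
#'
#' @param t time since repression (min); may be `Inf`.
#' @param wildtype_ratio RodA:PBP2 stoichiometry in the wild type.
#' @param overexpression_fold fold overexpression of PBP2.
#' @param residual_fraction residual expression fraction `f` in (0, 1].
#' @param doubling_time `t_d` (min).
#' @param bound_fraction optional bound fraction `b` for the per-bound
#'   ratio.
#' @param ratio optional measured RodA:PBP2 ratio overriding the decay model
#'   for the per-bound calculation.
#' @return list with `ratio0`, `ratio` (at `t`, or the supplied
#'   measurement) and `per_bound` (NA unless `bound_fraction` given).
#' @export
roda_depletion_ratio <- function(t = 0, wildtype_ratio = 1.35,
                                 overexpression_fold = 3,
                                 residual_fraction = 0.1, doubling_time = 90,
                                 bound_fraction = NULL, ratio = NULL) {
  f <- residual_fraction
  stopifnot(wildtype_ratio > 0, overexpression_fold > 0, f > 0, f <= 1,
            doubling_time > 0, all(t >= 0))
  ratio0 <- wildtype_ratio / overexpression_fold
  if (is.null(ratio)) ratio <- ratio0 * ((1 - f) * 2^(-t / doubling_time) + f)
  per_bound <- NA_real_
  if (!is.null(bound_fraction)) {
    if (any(bound_fraction <= 0)) stop("bound_fraction must be > 0")
    per_bound <- ratio / bound_fraction
  }
  list(ratio0 = ratio0, ratio = ratio, per_bound = per_bound)
}
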