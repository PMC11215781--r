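# Common reduction of ensemble representations to weighted conformations.
# Every ensemble average in the package (J-couplings, amide I' spectra) runs
# through this: a dihedral series becomes equally weighted frames, a
# histogram its non-empty bin centers, and a Gaussian mixture is first
# discretized onto the 2-degree grid (midpoint quadrature).
as_ensemble_weights <- function(ensemble) {
  if (inherits(ensemble, "rama_mixture")) {
    if (abs(sum(ensemble$weight) - 1) > 1e-9) {
      abort("mixture weights are not normalized")
    }
    ensemble <- mixture_histogram(ensemble)
  }
  if (inherits(ensemble, "rama_histogram")) {
    keep <- ensemble$prob > 0
    if (!any(keep)) abort("ensemble carries no probability mass")
    return(tibble(
      phi = ensemble$phi[keep], psi = ensemble$psi[keep],
      w = ensemble$prob[keep]
    ))
  }
  if (is.data.frame(ensemble) && all(c("phi", "psi", "w") %in% names(ensemble))) {
    return(as_tibble(ensemble)) # already reduced
  }
  s <- as_dihedral_series(ensemble)
  tibble(phi = s$phi, psi = s$psi, w = rep(1 / nrow(s), nrow(s)))
}
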