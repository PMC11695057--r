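#' Define a three-species competitive binding system
#'
#' A `competition_system` holds the fixed composition of a competition
#' experiment in which a ligand (total binding-site concentration `a_total`)
#' and a competitor (concentration supplied per curve point) partition a
#' limited pool of receptor (`r_total`). All concentrations are in nM;
#' mixed-unit construction is rejected.
#'
#' @param a_total Total ligand binding-site concentration (nM). For a
#'   disulfide-linked dimeric ligand with two independent sites, use
#'   [dimer_to_sites()] to convert the dimer concentration.
#' @param r_total Total receptor concentration (nM). May be zero.
#' @param ka Receptor-ligand equilibrium dissociation constant \eqn{K_A} (nM).
#' @param kb Competitor-ligand equilibrium dissociation constant \eqn{K_B}
#'   (nM). May be `NA` for a system in which \eqn{K_B} is to be fitted.
#' @param unit Concentration unit of all four arguments. Only `"nM"` is
#'   accepted; supplying values in different units is an error by design.
#'
#' @return An object of class `competition_system`.
#' @seealso [bound_fraction_no_competitor()], [wang_competition_curve()],
#'   [fit_competition_model()]
#' @examples
#' sys <- competition_system(a_total = 64, r_total = 50, ka = 10.4, kb = 200)
#' bound_fraction_no_competitor(sys)
#' @export
competition_system <- function(a_total, r_total, ka, kb = NA_real_,
                               unit = "nM") {
  if (!identical(unit, "nM")) {
    stop("all concentrations must be supplied in nM; got unit '", unit, "'")
  }
  stopifnot(is.numeric(a_total), length(a_total) == 1L,
            is.numeric(r_total), length(r_total) == 1L,
            is.numeric(ka), length(ka) == 1L,
            is.numeric(kb), length(kb) == 1L)
  if (!is.finite(a_total) || a_total <= 0) stop("a_total must be > 0")
  if (!is.finite(r_total) || r_total < 0) stop("r_total must be >= 0")
  if (!is.finite(ka) || ka <= 0) stop("ka must be > 0")
  if (!is.na(kb) && (!is.finite(kb) || kb <= 0)) {
    stop("kb must be > 0 (or NA when it is the quantity to be fitted)")
  }
  structure(
    list(a_total = as.numeric(a_total), r_total = as.numeric(r_total),
         ka = as.numeric(ka), kb = as.numeric(kb), unit = "nM"),
    class = "competition_system"
  )
}

#' @export
print.competition_system <- function(x, ...) {
  cat("Competitive binding system (all nM)\n")
  cat(sprintf("  ligand sites A : %g\n", x$a_total))
  cat(sprintf("  receptor R     : %g\n", x$r_total))
  cat(sprintf("  K_A            : %g\n", x$ka))
  cat(sprintf("  K_B            : %s\n",
              if (is.na(x$kb)) "(to be fitted)" else format(x$kb)))
  invisible(x)
}

#' Convert a dimer concentration to a binding-site concentration
#'
#' A disulfide-linked dimeric ligand presents two equivalent binding sites
#' per molecule; site-level models take the site concentration directly.
#' Protomer-level cooperativity is not modelled.
#'
#' @param dimer_conc Dimer concentration (nM).
#' @param sites_per_dimer Sites per dimer (default 2).
#' @return Site concentration (nM).
#' @examples
#' dimer_to_sites(32) # 64 nM of sites
#' @export
dimer_to_sites <- function(dimer_conc, sites_per_dimer = 2) {
  stopifnot(is.numeric(dimer_conc), all(dimer_conc >= 0),
            sites_per_dimer > 0)
  dimer_conc * sites_per_dimer
}
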