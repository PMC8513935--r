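# Free-energy mathematics: per-SSIP solvation in simple and two-domain
# solvents, whole-molecule solvation, transfer, 1:1 complexation, and the
# self-consistency relations linking solvent constants to the effective
# concentration of solvent-solvent interactions.

.as_solvent <- function(solvent) {
  if (is.character(solvent)) get_solvent(solvent) else solvent
}

#' Solvation free energy of a donor SSIP in a simple solvent
#'
#' Transfer of a single H-bond donor site of polarity `alpha` from the
#' non-solvated reference state into a one-site-pair solvent:
#' `dg = -alpha * beta_S - C_beta`.
#'
#' @param alpha Donor polarity (dimensionless, >= 0).
#' @param solvent A `simple_solvent` object or solvent name.
#' @return Free energy in kJ/mol.
#' @examples
#' dg_alpha_simple(1.20, "water")      # -3.40
#' dg_alpha_simple(1.20, "hexadecane") # -3.36
#' @export
dg_alpha_simple <- function(alpha, solvent) {
  solvent <- .as_solvent(solvent)
  stopifnot(inherits(solvent, "simple_solvent"), all(alpha >= 0))
  -alpha * solvent$beta_s - solvent$c_beta
}

#' Solvation free energy of an acceptor SSIP in a simple solvent
#'
#' Mirror of [dg_alpha_simple()] for H-bond acceptor sites:
#' `dg = -alpha_S * beta - C_alpha`.
#'
#' @param beta Acceptor polarity (dimensionless, >= 0).
#' @param solvent A `simple_solvent` object or solvent name.
#' @return Free energy in kJ/mol.
#' @examples
#' dg_beta_simple(0.60, "water") # -1.52
#' @export
dg_beta_simple <- function(beta, solvent) {
  solvent <- .as_solvent(solvent)
  stopifnot(inherits(solvent, "simple_solvent"), all(beta >= 0))
  -solvent$alpha_s * beta - solvent$c_alpha
}

.check_two_domain <- function(solvent) {
  if (!inherits(solvent, "two_domain_solvent")) {
    stop("a two-domain (polar) solvent is required", call. = FALSE)
  }
  if (is.null(solvent$f_beta1)) {
    stop("solvent carries no site fractions; request a class member via ",
         "get_solvent() (e.g. 'ethanol', not 'alcohols')", call. = FALSE)
  }
  solvent
}

#' Solvation free energy of a donor SSIP in a two-domain solvent
#'
#' A solute donor site in a polar solvent equilibrates between solvation by
#' the non-polar acceptor sites (`beta_S1`, `C_beta1`) and the polar
#' acceptor sites (`beta_S2`, `C_beta2`). Each mode contributes an
#' effective equilibrium constant `K_i = exp((alpha*beta_Si + C_beta_i)/RT)`
#' and the modes combine weighted by the fraction of acceptor sites of each
#' type in the member solvent molecule:
#' `dg = -RT * log(f_beta1*K1 + f_beta2*K2)`.
#'
#' @param alpha Donor polarity (>= 0).
#' @param solvent A `two_domain_solvent` carrying member site fractions, or
#'   a member solvent name (e.g. "tetrahydrofuran").
#' @param constants A [model_constants()] object.
#' @return Free energy in kJ/mol.
#' @export
dg_alpha_polar <- function(alpha, solvent, constants = model_constants()) {
  solvent <- .check_two_domain(.as_solvent(solvent))
  stopifnot(all(alpha >= 0))
  rt <- rt_kj(constants)
  k1 <- exp((alpha * solvent$beta_s1 + solvent$c_beta1) / rt)
  k2 <- exp((alpha * solvent$beta_s2 + solvent$c_beta2) / rt)
  -rt * log(solvent$f_beta1 * k1 + solvent$f_beta2 * k2)
}

#' Solvation free energy of an acceptor SSIP in a two-domain solvent
#'
#' Mirror of [dg_alpha_polar()] using the solvent's donor sites
#' (`alpha_S1`, `C_alpha1`) and (`alpha_S2`, `C_alpha2`) with the donor
#' site fractions. Ethers have no polar donor site (`f_alpha2 = 0`), so the
#' expression collapses to the simple-solvent form with the non-polar donor
#' parameters.
#'
#' @param beta Acceptor polarity (>= 0).
#' @param solvent A `two_domain_solvent` with member site fractions, or a
#'   member solvent name.
#' @param constants A [model_constants()] object.
#' @return Free energy in kJ/mol.
#' @export
dg_beta_polar <- function(beta, solvent, constants = model_constants()) {
  solvent <- .check_two_domain(.as_solvent(solvent))
  stopifnot(all(beta >= 0))
  rt <- rt_kj(constants)
  k1 <- exp((solvent$alpha_s1 * beta + solvent$c_alpha1) / rt)
  if (solvent$f_alpha2 == 0) {
    k2 <- 0
  } else {
    if (is.na(solvent$alpha_s2)) {
      stop("solvent class '", solvent$class_name,
           "' has no polar donor site but f_alpha2 > 0", call. = FALSE)
    }
    k2 <- exp((solvent$alpha_s2 * beta + solvent$c_alpha2) / rt)
  }
  -rt * log(solvent$f_alpha1 * k1 + solvent$f_alpha2 * k2)
}

#' Solvation free energy of one donor SSIP in any registered solvent
#' @inheritParams dg_alpha_polar
#' @return kJ/mol; dispatches to the simple or two-domain expression.
#' @export
dg_alpha <- function(alpha, solvent, constants = model_constants()) {
  solvent <- .as_solvent(solvent)
  if (inherits(solvent, "simple_solvent")) dg_alpha_simple(alpha, solvent)
  else dg_alpha_polar(alpha, solvent, constants)
}

#' Solvation free energy of one acceptor SSIP in any registered solvent
#' @inheritParams dg_beta_polar
#' @return kJ/mol; dispatches to the simple or two-domain expression.
#' @export
dg_beta <- function(beta, solvent, constants = model_constants()) {
  solvent <- .as_solvent(solvent)
  if (inherits(solvent, "simple_solvent")) dg_beta_simple(beta, solvent)
  else dg_beta_polar(beta, solvent, constants)
}

#' Whole-molecule solvation free energy
#'
#' Sums the per-SSIP solvation free energies of a solute profile in a
#' solvent and applies the solvent's intrinsic offset once per molecule:
#' `dG* = sum(dg) - C0`. `C0` is defined relative to n-hexadecane and a
#' positive value makes solvation in that solvent more favourable. The
#' result is the free energy of the solute in the solvent relative to the
#' common non-solvated reference state; only differences between solvents
#' (transfer free energies) are physically observable.
#'
#' @param profile A [build_ssip_profile()] result (or SMILES string).
#' @param solvent Solvent name or descriptor object.
#' @param constants A [model_constants()] object.
#' @return A `solvation_breakdown`: per-SSIP contributions, their sum, the
#'   `C0` term and the total `dg_total` (kJ/mol).
#' @examples
#' solvation_free_energy(build_ssip_profile("C"), "water")
#' @export
solvation_free_energy <- function(profile, solvent,
                                  constants = model_constants()) {
  if (is.character(profile)) profile <- build_ssip_profile(profile)
  stopifnot(inherits(profile, "ssip_profile"))
  solvent <- .as_solvent(solvent)

  s <- profile$ssips
  dg <- numeric(nrow(s))
  if (nrow(s)) {
    don <- s$role == "donor"
    if (any(don)) dg[don] <- dg_alpha(s$value[don], solvent, constants)
    if (any(!don)) dg[!don] <- dg_beta(s$value[!don], solvent, constants)
  }
  per_site <- cbind(s[, c("role", "value", "count", "label", "code")],
                    dg_per_ssip = dg, dg_contribution = dg * s$count)
  sum_dg <- sum(per_site$dg_contribution)
  total <- sum_dg - solvent$c0

  structure(
    list(id = profile$id,
         solvent = if (inherits(solvent, "simple_solvent")) solvent$name
                   else solvent$member,
         per_site = per_site,
         sum_dg = sum_dg,
         c0 = solvent$c0,
         dg_total = total),
    class = "solvation_breakdown"
  )
}

#' @export
print.solvation_breakdown <- function(x, ...) {
  cat(sprintf("Solvation of %s in %s\n", x$id, x$solvent))
  p <- x$per_site
  for (i in seq_len(nrow(p))) {
    cat(sprintf("  %2d x %-5s %5.2f  %-18s dg = %7.2f  (sum %7.2f) kJ/mol\n",
                p$count[i], if (p$role[i] == "donor") "alpha" else "beta",
                p$value[i], p$label[i], p$dg_per_ssip[i],
                p$dg_contribution[i]))
  }
  cat(sprintf("  sum(dg) = %.2f, C0 = %.2f, dG* = %.2f kJ/mol\n",
              x$sum_dg, x$c0, x$dg_total))
  invisible(x)
}

#' Solvent-to-solvent transfer free energy and partition coefficient
#'
#' `dG(S1 -> S2) = dG*(S2) - dG*(S1)`; the partition coefficient follows as
#' `logP = -dG / (RT ln 10)` with P defined as the concentration in the
#' destination solvent over the concentration in the source solvent
#' (1 M standard states).
#'
#' @param profile A [build_ssip_profile()] result or SMILES string.
#' @param solvent_from,solvent_to Solvent names or descriptor objects.
#' @param constants A [model_constants()] object.
#' @return A `transfer_result` with `dg_kjmol` and `logp`.
#' @examples
#' transfer_free_energy("CCCCCCC", "hexadecane", "water") # +28.7 kJ/mol
#' @export
transfer_free_energy <- function(profile, solvent_from, solvent_to,
                                 constants = model_constants()) {
  if (is.character(profile)) profile <- build_ssip_profile(profile)
  from <- .as_solvent(solvent_from)
  to <- .as_solvent(solvent_to)
  g_from <- solvation_free_energy(profile, from, constants)
  g_to <- solvation_free_energy(profile, to, constants)
  dg <- g_to$dg_total - g_from$dg_total
  structure(
    list(id = profile$id,
         solvent_from = g_from$solvent,
         solvent_to = g_to$solvent,
         dg_kjmol = dg,
         logp = -dg / (rt_kj(constants) * log(10))),
    class = "transfer_result"
  )
}

#' @export
print.transfer_result <- function(x, ...) {
  cat(sprintf("%s: %s -> %s  dG = %+.2f kJ/mol  (logP = %+.2f)\n",
              x$id, x$solvent_from, x$solvent_to, x$dg_kjmol, x$logp))
  invisible(x)
}

#' Free energy of 1:1 H-bond complexation in a non-polar solvent
#'
#' Solvent-competition expression for formation of a single hydrogen bond
#' between a donor of polarity `alpha` and an acceptor of polarity `beta`:
#' `dG = -alpha*beta + alpha*beta_S + alpha_S*beta + C_alpha + C_beta`.
#' For solvents whose constants satisfy
#' `C_alpha + C_beta = 6 - alpha_S*beta_S` this is identical to the compact
#' form `dG = -(alpha - alpha_S)(beta - beta_S) + 6`, which is also
#' reported for comparison. The model is validated against 1:1 complexation
#' data in non-polar solvents only, so two-domain solvents are refused.
#'
#' @param alpha,beta Solute donor and acceptor polarities (>= 0).
#' @param solvent A `simple_solvent` object or name.
#' @param constants A [model_constants()] object.
#' @return A `complexation_result` with `dg_kjmol`, the compact-form value
#'   `dg_eq_compact`, and the association constant `k_assoc` (M^-1, 1 M
#'   standard state).
#' @examples
#' complexation_dg(2.80, 4.50, "carbon tetrachloride") # +0.54 kJ/mol
#' @export
complexation_dg <- function(alpha, beta, solvent,
                            constants = model_constants()) {
  solvent <- .as_solvent(solvent)
  if (inherits(solvent, "two_domain_solvent")) {
    stop("1:1 complexation free energies are only supported in non-polar ",
         "(simple) solvents; '", solvent$class_name,
         "' is a two-domain solvent", call. = FALSE)
  }
  stopifnot(inherits(solvent, "simple_solvent"), alpha >= 0, beta >= 0)
  dg <- -alpha * beta + alpha * solvent$beta_s + solvent$alpha_s * beta +
    solvent$c_alpha + solvent$c_beta
  dg_compact <- -(alpha - solvent$alpha_s) * (beta - solvent$beta_s) +
    constants$reference_ss_entropy
  structure(
    list(alpha = alpha, beta = beta, solvent = solvent$name,
         dg_kjmol = dg, dg_eq_compact = dg_compact,
         k_assoc = exp(-dg / rt_kj(constants))),
    class = "complexation_result"
  )
}

#' @export
print.complexation_result <- function(x, ...) {
  cat(sprintf(
    "1:1 complex (alpha %.2f + beta %.2f) in %s: dG = %+.2f kJ/mol, K = %.3g M^-1\n",
    x$alpha, x$beta, x$solvent, x$dg_kjmol, x$k_assoc))
  invisible(x)
}

#' Effective solvent-solvent interaction term RT ln[S.S]
#'
#' Back-calculates the entropic free-energy equivalent of the effective
#' concentration of solvent-solvent interactions from a solvent's
#' constants: `RT ln[S.S] = C_alpha + C_beta + alpha_S*beta_S`. For
#' two-domain solvents the relation is applied within one solvating domain
#' (1 = non-polar, 2 = polar).
#'
#' @param solvent Solvent name or descriptor object.
#' @param domain For two-domain solvents, which domain to evaluate (1 or 2).
#' @return RT ln\[S.S\] in kJ/mol.
#' @examples
#' rt_ln_ss("hexadecane") # 6.0
#' rt_ln_ss("chloroform") # 6.6
#' @export
rt_ln_ss <- function(solvent, domain = NULL) {
  solvent <- .as_solvent(solvent)
  if (inherits(solvent, "simple_solvent")) {
    return(solvent$c_alpha + solvent$c_beta + solvent$alpha_s * solvent$beta_s)
  }
  if (is.null(domain) || !domain %in% c(1, 2)) {
    stop("for a two-domain solvent, give domain = 1 (non-polar) or 2 (polar)",
         call. = FALSE)
  }
  if (domain == 1) {
    solvent$c_alpha1 + solvent$c_beta1 + solvent$alpha_s1 * solvent$beta_s1
  } else {
    if (is.na(solvent$alpha_s2)) {
      stop("solvent class '", solvent$class_name,
           "' has no polar donor site; domain 2 closure is undefined",
           call. = FALSE)
    }
    solvent$c_alpha2 + solvent$c_beta2 + solvent$alpha_s2 * solvent$beta_s2
  }
}

#' Solvent constants from the solvent-solvent interaction concentration
#'
#' For a solvent with a single type of solvent-solvent interaction (alkanes,
#' carbon tetrachloride, perfluoroalkanes, water) the two constants are
#' equal and follow in closed form:
#' `C_alpha = C_beta = (-alpha_S*beta_S + RT ln[S.S]) / 2`.
#'
#' @param alpha_s,beta_s Solvent H-bond parameters.
#' @param ss_concentration Effective molar concentration of solvent-solvent
#'   interactions \[S.S\] (mol/L). Give either this or `rt_ln_ss_kj`.
#' @param rt_ln_ss_kj `RT ln[S.S]` directly in kJ/mol (e.g. the +6 kJ/mol
#'   reference value).
#' @param constants A [model_constants()] object.
#' @return Named vector `c(c_alpha = , c_beta = )` in kJ/mol.
#' @examples
#' constants_from_ss(1.20, 0.60, rt_ln_ss_kj = 6)    # alkanes: 2.64
#' constants_from_ss(2.80, 4.50, ss_concentration = 110) # water: -0.47
#' @export
constants_from_ss <- function(alpha_s, beta_s, ss_concentration = NULL,
                              rt_ln_ss_kj = NULL,
                              constants = model_constants()) {
  stopifnot(alpha_s > 0, beta_s > 0)
  if (is.null(rt_ln_ss_kj)) {
    if (is.null(ss_concentration) || ss_concentration <= 0) {
      stop("give a positive 'ss_concentration' or 'rt_ln_ss_kj'",
           call. = FALSE)
    }
    rt_ln_ss_kj <- rt_kj(constants) * log(ss_concentration)
  }
  c_val <- (-alpha_s * beta_s + rt_ln_ss_kj) / 2
  c(c_alpha = c_val, c_beta = c_val)
}
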