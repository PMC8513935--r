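# Parameter registry: solvent descriptors, functional-group SSIP templates,
# aromatic pi-face values and liquid molar densities, loaded once per session
# from the CSV tables shipped under extdata. All numeric parameter values
# live in those files, never in code.

.ssip_env <- new.env(parent = emptyenv())

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "ssipsolv")
  if (!nzchar(path)) {
    # during development (pkgload) fall back to the source tree
    path <- file.path("inst", "extdata", file)
  }
  if (!file.exists(path)) stop("parameter file not found: ", file, call. = FALSE)
  path
}

.read_table <- function(file) {
  utils::read.csv(.extdata(file), stringsAsFactors = FALSE, check.names = FALSE)
}

#' @keywords internal
.ssip_registry <- function(force = FALSE) {
  if (!force && !is.null(.ssip_env$registry)) return(.ssip_env$registry)

  simple_long <- .read_table("solvents_simple.csv")
  simple <- lapply(split(simple_long, simple_long$solvent), function(d) {
    vals <- stats::setNames(as.numeric(d$value), d$field)
    structure(
      list(name = d$solvent[[1]],
           alpha_s = vals[["alpha_s"]], c_alpha = vals[["c_alpha"]],
           beta_s = vals[["beta_s"]], c_beta = vals[["c_beta"]],
           c0 = vals[["c0"]],
           provenance = stats::setNames(d$provenance, d$field)),
      class = "simple_solvent"
    )
  })

  polar_long <- .read_table("solvents_polar.csv")
  polar <- lapply(split(polar_long, polar_long$class), function(d) {
    vals <- stats::setNames(suppressWarnings(as.numeric(d$value)), d$field)
    structure(
      list(class_name = d$class[[1]],
           alpha_s1 = vals[["alpha_s1"]], c_alpha1 = vals[["c_alpha1"]],
           beta_s1 = vals[["beta_s1"]], c_beta1 = vals[["c_beta1"]],
           alpha_s2 = vals[["alpha_s2"]], c_alpha2 = vals[["c_alpha2"]],
           beta_s2 = vals[["beta_s2"]], c_beta2 = vals[["c_beta2"]],
           c0 = vals[["c0"]],
           provenance = stats::setNames(d$provenance, d$field)),
      class = "two_domain_solvent"
    )
  })

  members <- .read_table("polar_members.csv")
  groups <- .read_table("groups.csv")
  pi_faces <- .read_table("pi_faces.csv")
  liquids <- .read_table("liquids.csv")
  synonyms <- .read_table("solvent_synonyms.csv")

  reg <- list(
    simple = simple,
    polar = polar,
    members = members,
    groups = groups,
    pi_faces = pi_faces,
    liquids = liquids,
    synonyms = stats::setNames(synonyms$canonical, tolower(synonyms$synonym)),
    site_fraction_cache = new.env(parent = emptyenv())
  )
  .ssip_env$registry <- reg
  reg
}

.resolve_solvent_name <- function(name, registry = .ssip_registry()) {
  key <- tolower(trimws(name))
  if (key %in% names(registry$synonyms)) key <- registry$synonyms[[key]]
  key
}

#' Look up a solvent descriptor set
#'
#' Retrieves the descriptors of a registered solvent. Non-polar solvents and
#' water are described by a single donor/acceptor site pair
#' (`alpha_s`, `beta_s`) with constants `c_alpha`, `c_beta` and an offset
#' `c0` relative to n-hexadecane. Polar solvents (ethers, nitriles, ketones,
#' alcohols) are two-domain solvents: a non-polar hydrocarbon site type
#' (subscript 1) and a polar site type (subscript 2), combined via the
#' fractions of donor and acceptor sites of each type in the particular
#' member solvent molecule.
#'
#' @param name Solvent name (case-insensitive; common synonyms such as
#'   "n-hexadecane" or "THF" are accepted). For a two-domain solvent the
#'   name of a class member (e.g. "ethanol") returns the class constants
#'   together with that member's site fractions.
#' @return A `simple_solvent` or `two_domain_solvent` object. Two-domain
#'   solvents carry `member`, and site fractions `f_alpha1`, `f_alpha2`,
#'   `f_beta1`, `f_beta2`.
#' @examples
#' get_solvent("chloroform")
#' get_solvent("ethanol")
#' @export
get_solvent <- function(name) {
  registry <- .ssip_registry()
  key <- .resolve_solvent_name(name, registry)
  if (key %in% names(registry$simple)) return(registry$simple[[key]])

  m <- registry$members[tolower(registry$members$member) == key, , drop = FALSE]
  if (nrow(m) == 1L) {
    sol <- registry$polar[[m$class]]
    sol$member <- m$member
    sol$member_smiles <- m$smiles
    fr <- .member_site_fractions(m$member, m$smiles, registry)
    sol[names(fr)] <- fr
    return(sol)
  }
  if (key %in% names(registry$polar)) {
    stop("'", name, "' is a solvent class; request one of its members: ",
         paste(registry$members$member[registry$members$class == key],
               collapse = ", "), call. = FALSE)
  }
  known <- list_solvents()
  dist <- utils::adist(key, tolower(known))
  nearest <- known[order(dist)][seq_len(min(3L, length(known)))]
  stop("unknown solvent '", name, "'; nearest registered matches: ",
       paste(nearest, collapse = ", "), call. = FALSE)
}

# Acceptor/donor site fractions of a polar-class member, computed from the
# SSIP profile of the member molecule itself: sites contributed by the
# class-defining polar group count towards domain 2, CH-derived (and other
# non-polar) sites towards domain 1.
.member_site_fractions <- function(member, smiles, registry) {
  cache <- registry$site_fraction_cache
  if (!is.null(cache[[member]])) return(cache[[member]])
  prof <- build_ssip_profile(smiles, id = member)
  s <- prof$ssips
  f <- function(role, domain) sum(s$count[s$role == role & s$domain == domain])
  n_a1 <- f("donor", "nonpolar"); n_a2 <- f("donor", "polar")
  n_b1 <- f("acceptor", "nonpolar"); n_b2 <- f("acceptor", "polar")
  fr <- list(
    f_alpha1 = n_a1 / (n_a1 + n_a2), f_alpha2 = n_a2 / (n_a1 + n_a2),
    f_beta1 = n_b1 / (n_b1 + n_b2), f_beta2 = n_b2 / (n_b1 + n_b2)
  )
  cache[[member]] <- fr
  fr
}

#' List all registered solvents
#'
#' @param polar_members If `TRUE` (default) include the members of the polar
#'   solvent classes; otherwise list simple solvents and class names only.
#' @return Character vector of registered solvent names, simple solvents
#'   first (in registry order), then polar members.
#' @export
list_solvents <- function(polar_members = TRUE) {
  registry <- .ssip_registry()
  simple <- unique(.read_order_simple(registry))
  if (polar_members) c(simple, registry$members$member)
  else c(simple, names(registry$polar))
}

# printed-table order, for diff-stable sweeps
.read_order_simple <- function(registry) {
  long <- .read_table("solvents_simple.csv")
  unique(long$solvent)
}

#' Look up a functional-group SSIP template
#'
#' Returns the SSIP description of one atom environment: the multiset of
#' donor (alpha) and acceptor (beta) interaction points that the atom
#' contributes to a molecule's profile.
#'
#' @param group_code Atom-environment code in the SMARTS-like nomenclature
#'   used by [assign_atom_codes()], e.g. `"[CX4H3]"` for an sp3 CH3 carbon.
#' @return A `group_params` object: the code and a data frame `ssips` with
#'   columns `role` ("donor"/"acceptor"), `value`, `count`, `label`,
#'   `domain` and `provenance`.
#' @examples
#' get_group_params("[cH]")     # aromatic CH: one alpha 1.40, two beta 0.70
#' get_group_params("[OX2H1]")  # alcohol OH: alpha 2.70, beta 5.30 and 3.98
#' @export
get_group_params <- function(group_code) {
  registry <- .ssip_registry()
  g <- registry$groups
  rows <- g[g$code == group_code, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("unknown group code '", group_code, "'; registered codes: ",
         paste(unique(g$code), collapse = ", "), call. = FALSE)
  }
  ssips <- rows[rows$role %in% c("donor", "acceptor"), , drop = FALSE]
  structure(
    list(code = group_code,
         ssips = ssips[, c("role", "value", "count", "label", "domain",
                           "provenance")]),
    class = "group_params"
  )
}

#' List all registered atom-environment codes
#' @return Character vector of group codes.
#' @export
list_group_codes <- function() {
  unique(.ssip_registry()$groups$code)
}

#' Pi-face acceptor value for a six-membered aromatic ring
#'
#' Each six-membered aromatic ring carries two additional acceptor SSIPs,
#' one over the centre of each face of the pi system. Their polarity grows
#' with the number of alkyl substituents on the ring (benzene 2.00 up to
#' hexamethylbenzene 3.10). Substitution patterns outside the calibrated
#' table raise an error rather than defaulting silently.
#'
#' @param n_alkyl Number of alkyl substituents on the ring (0, 1, 2, 3 or 6).
#' @return The beta value of each of the two ring-centre SSIPs.
#' @examples
#' pi_face_beta(0) # benzene, 2.00
#' pi_face_beta(1) # toluene, 2.20
#' @export
pi_face_beta <- function(n_alkyl) {
  tab <- .ssip_registry()$pi_faces
  hit <- match(n_alkyl, tab$n_alkyl)
  if (is.na(hit)) {
    stop("no calibrated pi-face value for a six-membered aromatic ring with ",
         n_alkyl, " alkyl substituents (calibrated: ",
         paste(tab$n_alkyl, collapse = ", "), ")", call. = FALSE)
  }
  tab$beta[[hit]]
}

#' Molar concentration of a registered pure liquid
#'
#' @param name Liquid name (same synonyms as [get_solvent()]).
#' @return Molar concentration in mol L^-1, from the shipped molar mass and
#'   density table.
#' @examples
#' liquid_molarity("water") # about 55 M
#' @export
liquid_molarity <- function(name) {
  registry <- .ssip_registry()
  key <- .resolve_solvent_name(name, registry)
  liq <- registry$liquids
  hit <- match(key, tolower(liq$name))
  if (is.na(hit)) {
    stop("no molar density registered for '", name, "'; available: ",
         paste(liq$name, collapse = ", "), call. = FALSE)
  }
  1000 * liq$density[[hit]] / liq$molar_mass[[hit]]
}

#' @export
print.simple_solvent <- function(x, ...) {
  cat(sprintf("Simple solvent: %s\n", x$name))
  cat(sprintf("  alpha_S = %.2f  C_alpha = %+.2f kJ/mol\n", x$alpha_s, x$c_alpha))
  cat(sprintf("  beta_S  = %.2f  C_beta  = %+.2f kJ/mol\n", x$beta_s, x$c_beta))
  cat(sprintf("  C0      = %+.2f kJ/mol\n", x$c0))
  invisible(x)
}

#' @export
print.two_domain_solvent <- function(x, ...) {
  cat(sprintf("Two-domain solvent class: %s", x$class_name))
  if (!is.null(x$member)) cat(sprintf("  (member: %s)", x$member))
  cat("\n")
  cat(sprintf("  non-polar sites: alpha_S1 = %.2f (C %+.2f), beta_S1 = %.2f (C %+.2f)\n",
              x$alpha_s1, x$c_alpha1, x$beta_s1, x$c_beta1))
  a2 <- if (is.na(x$alpha_s2)) "     --        " else
    sprintf("alpha_S2 = %.2f (C %+.2f)", x$alpha_s2, x$c_alpha2)
  cat(sprintf("  polar sites:     %s, beta_S2 = %.2f (C %+.2f)\n",
              a2, x$beta_s2, x$c_beta2))
  cat(sprintf("  C0 = %+.2f kJ/mol\n", x$c0))
  if (!is.null(x$f_beta1)) {
    cat(sprintf("  site fractions: f_alpha = (%.3f, %.3f), f_beta = (%.3f, %.3f)\n",
                x$f_alpha1, x$f_alpha2, x$f_beta1, x$f_beta2))
  }
  invisible(x)
}

#' @export
print.group_params <- function(x, ...) {
  cat(sprintf("Group %s:\n", x$code))
  for (i in seq_len(nrow(x$ssips))) {
    r <- x$ssips[i, ]
    cat(sprintf("  %d x %s %s = %.2f  [%s, %s]\n", r$count,
                if (r$role == "donor") "alpha" else "beta",
                r$label, r$value, r$domain, r$provenance))
  }
  invisible(x)
}
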