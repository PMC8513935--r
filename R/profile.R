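# SSIP profiles: the multiset of interaction points representing a solute.

#' Build the SSIP profile of a molecule
#'
#' Assembles the full multiset of surface site interaction points of a
#' molecule by summing the per-atom functional-group templates and adding
#' two ring-centre acceptor SSIPs (one per face) for every six-membered
#' aromatic ring, with the face value chosen by the ring's alkyl
#' substitution pattern.
#'
#' @param x A SMILES string or a [parse_structure()] graph.
#' @param codes Optional pre-computed codes from [assign_atom_codes()];
#'   computed from `x` when `NULL`.
#' @param id Optional molecule identifier carried into results.
#' @return A `ssip_profile`: list with `id`, `smiles`, `ssips` (data frame
#'   with `role`, `value`, `count`, `label`, `code`, `domain`), and the
#'   derived counts `n_alpha`, `n_beta`, `n_rings`.
#' @examples
#' p <- build_ssip_profile("c1ccccc1")
#' p$n_alpha + p$n_beta # benzene: 20 SSIPs
#' @export
build_ssip_profile <- function(x, codes = NULL, id = NULL) {
  graph <- if (inherits(x, "molecule_graph")) x else parse_structure(x)
  if (is.null(codes)) codes <- assign_atom_codes(graph)
  if (length(codes) != nrow(graph$atoms)) {
    stop("'codes' must have one entry per heavy atom", call. = FALSE)
  }

  rows <- list()
  for (i in seq_along(codes)) {
    tmpl <- get_group_params(codes[i])$ssips
    if (nrow(tmpl)) {
      tmpl$code <- codes[i]
      rows[[length(rows) + 1L]] <- tmpl
    }
  }

  n_rings <- length(graph$rings6)
  if (n_rings) {
    for (ring in graph$rings6) {
      n_alkyl <- sum(codes[ring] == "[c;alkyl]")
      rows[[length(rows) + 1L]] <- data.frame(
        role = "acceptor", value = pi_face_beta(n_alkyl), count = 2L,
        label = "pi(ring centre)", domain = "nonpolar",
        provenance = "experimental_1to1", code = "ring.pi6"
      )
    }
  }

  ssips <- do.call(rbind, rows)
  if (is.null(ssips)) {
    ssips <- data.frame(role = character(), value = numeric(),
                        count = integer(), label = character(),
                        domain = character(), provenance = character(),
                        code = character())
  } else {
    # aggregate identical (role, value, label, code) rows into one multiset row
    key <- paste(ssips$role, ssips$value, ssips$label, ssips$code, sep = "|")
    agg <- lapply(split(ssips, key), function(d) {
      d$count[1] <- sum(d$count); d[1, , drop = FALSE]
    })
    ssips <- do.call(rbind, agg)
    ssips <- ssips[order(ssips$role, -ssips$value, ssips$code), , drop = FALSE]
    rownames(ssips) <- NULL
  }

  structure(
    list(id = if (is.null(id)) graph$smiles else id,
         smiles = graph$smiles,
         ssips = ssips[, c("role", "value", "count", "label", "code",
                           "domain", "provenance")],
         n_alpha = sum(ssips$count[ssips$role == "donor"]),
         n_beta = sum(ssips$count[ssips$role == "acceptor"]),
         n_rings = n_rings),
    class = "ssip_profile"
  )
}

#' Total SSIP count of a profile
#' @param profile A [build_ssip_profile()] result.
#' @return `n_alpha + n_beta`.
#' @export
n_ssips <- function(profile) {
  stopifnot(inherits(profile, "ssip_profile"))
  profile$n_alpha + profile$n_beta
}

# expand the multiset into per-site value vectors
.profile_values <- function(profile) {
  s <- profile$ssips
  list(alpha = rep(s$value[s$role == "donor"], s$count[s$role == "donor"]),
       beta = rep(s$value[s$role == "acceptor"], s$count[s$role == "acceptor"]))
}

#' Advisory SSIP count from the molar concentration of a pure liquid
#'
#' The number of SSIPs assigned per molecule is anchored so that the total
#' SSIP concentration of a pure liquid is roughly constant (about 220 M,
#' the value for liquid water with 4 sites at 55 M). This helper returns
#' the integer count implied by a liquid's molar concentration; it is a
#' design check on the functional-group templates, not an override of them.
#'
#' @param molar_concentration Molar concentration of the pure liquid
#'   (mol/L).
#' @param constants A [model_constants()] object.
#' @return Integer: `round(220 / molar_concentration)` (ties to even).
#' @examples
#' ssip_count_from_liquid(55)   # water: 4
#' ssip_count_from_liquid(11.2) # benzene: 20
#' @export
ssip_count_from_liquid <- function(molar_concentration,
                                   constants = model_constants()) {
  if (!is.numeric(molar_concentration) || molar_concentration <= 0) {
    stop("'molar_concentration' must be > 0", call. = FALSE)
  }
  as.integer(round(constants$target_ssip_concentration / molar_concentration))
}

#' Total SSIP concentration of a pure liquid
#'
#' @param profile SSIP profile of the liquid's molecule.
#' @param molar_concentration Molar concentration of the pure liquid
#'   (mol/L).
#' @return `(n_alpha + n_beta) * molar_concentration`, in mol/L.
#' @examples
#' p <- build_ssip_profile("ClCCl") # dichloromethane, 14 SSIPs
#' ssip_concentration(p, 15.6)      # about 219 M
#' @export
ssip_concentration <- function(profile, molar_concentration) {
  stopifnot(inherits(profile, "ssip_profile"))
  if (!is.numeric(molar_concentration) || molar_concentration <= 0) {
    stop("'molar_concentration' must be > 0", call. = FALSE)
  }
  n_ssips(profile) * molar_concentration
}

#' @export
print.ssip_profile <- function(x, ...) {
  cat(sprintf("SSIP profile: %s (%s)\n", x$id, x$smiles))
  cat(sprintf("  N_alpha = %d, N_beta = %d (total %d; %d aromatic ring%s)\n",
              x$n_alpha, x$n_beta, n_ssips(x), x$n_rings,
              if (x$n_rings == 1) "" else "s"))
  s <- x$ssips
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %2d x %-5s %5.2f  %-18s %s\n", s$count[i],
                if (s$role[i] == "donor") "alpha" else "beta",
                s$value[i], s$label[i], s$code[i]))
  }
  invisible(x)
}

#' Flatten an SSIP profile to a one-row-per-site table
#'
#' @param x A `ssip_profile`.
#' @param ... Unused.
#' @return Data frame with one row per individual SSIP (`id`, `smiles`,
#'   `role`, `value`, `label`, `code`).
#' @export
as.data.frame.ssip_profile <- function(x, ...) {
  s <- x$ssips
  idx <- rep(seq_len(nrow(s)), s$count)
  out <- s[idx, c("role", "value", "label", "code"), drop = FALSE]
  rownames(out) <- NULL
  cbind(id = x$id, smiles = x$smiles, out)
}
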