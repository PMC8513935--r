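# Structure analysis: SMILES -> molecular graph -> per-atom environment
# codes. Parsing, ring perception and aromaticity detection are delegated to
# ChemmineR/ChemmineOB (OpenBabel); implicit hydrogen counts are recomputed
# from standard valences because the kekulised SDF omits them.

.standard_valence <- c(C = 4L, N = 3L, O = 2L, S = 2L, F = 1L, Cl = 1L,
                       Br = 1L, I = 1L, P = 3L)

#' Parse a SMILES string into a molecular graph
#'
#' Builds the heavy-atom graph used for SSIP assignment: elements, bond
#' orders, implicit hydrogen counts, aromatic flags and six-membered
#' aromatic rings. Only neutral, non-isotopic molecules are supported.
#'
#' @param smiles A single SMILES string.
#' @return A `molecule_graph`: list with `smiles`, `atoms` (data frame with
#'   `idx`, `element`, `aromatic`, `n_h`), `bonds` (data frame with `a1`,
#'   `a2`, `order`) and `rings6` (list of integer vectors, the atom indices
#'   of each six-membered aromatic ring).
#' @examples
#' g <- parse_structure("c1ccccc1")
#' nrow(g$atoms)      # 6
#' length(g$rings6)   # 1
#' @export
parse_structure <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(trimws(smiles))) {
    stop("'smiles' must be a single non-empty string", call. = FALSE)
  }
  smiles <- trimws(smiles)
  if (grepl("\\[[^]]*[+-][^]]*\\]", smiles)) {
    stop("charged species are not supported: ", smiles, call. = FALSE)
  }
  if (grepl("\\[[0-9]+[A-Za-z]", smiles)) {
    stop("isotopically labelled species are not supported: ", smiles,
         call. = FALSE)
  }

  # single heavy atoms (e.g. water "O", methane "C"): the zero-bond molfile
  # trips the SDF reader, so build the one-atom graph directly
  if (grepl("^\\[?([A-Z][a-z]?)H?[0-9]?\\]?$", smiles)) {
    el <- sub("^\\[?([A-Z][a-z]?).*$", "\\1", smiles)
    if (!el %in% names(.standard_valence)) {
      stop("unsupported element in '", smiles, "'", call. = FALSE)
    }
    return(structure(
      list(smiles = smiles,
           atoms = data.frame(idx = 1L, element = el, aromatic = FALSE,
                              n_h = .standard_valence[[el]]),
           bonds = data.frame(a1 = integer(), a2 = integer(),
                              order = integer()),
           rings6 = list()),
      class = "molecule_graph"
    ))
  }

  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) stop("SMILES parse failure for '", smiles, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  mol <- sdf[[1]]
  ab <- ChemmineR::atomblock(mol)
  if (is.null(ab) || nrow(ab) == 0L) {
    stop("SMILES parse failure for '", smiles, "': no atoms", call. = FALSE)
  }
  element <- sub("_.*$", "", rownames(ab))
  n <- nrow(ab)

  bb <- ChemmineR::bondblock(mol)
  if (is.null(bb) || nrow(bb) == 0L) {
    bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer())
  } else {
    bonds <- data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]))
  }

  unknown <- setdiff(unique(element), names(.standard_valence))
  if (length(unknown)) {
    stop("unsupported element(s) in '", smiles, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  order_sum <- integer(n)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      order_sum[bonds$a1[k]] <- order_sum[bonds$a1[k]] + bonds$order[k]
      order_sum[bonds$a2[k]] <- order_sum[bonds$a2[k]] + bonds$order[k]
    }
  }
  n_h <- .standard_valence[element] - order_sum
  if (any(n_h < 0L)) {
    stop("valence inconsistency in '", smiles, "' (atom ",
         which(n_h < 0L)[1], ")", call. = FALSE)
  }

  # six-membered aromatic rings: ring perception from ChemmineR, aromaticity
  # decided on the Kekule structure (all-carbon ring, exactly three ring
  # double bonds, one per ring atom)
  rings6 <- list()
  aromatic <- rep(FALSE, n)
  if (n >= 6L && nrow(bonds) >= 6L) {
    rr <- tryCatch(ChemmineR::rings(mol, type = "all", arom = FALSE),
                   error = function(e) NULL)
    if (!is.null(rr)) {
      ring_list <- if (is.list(rr) && !is.null(rr$RINGS)) rr$RINGS else rr
      for (ring in ring_list) {
        idx <- sort(as.integer(sub("^.*_", "", ring)))
        if (length(idx) != 6L || !all(element[idx] == "C")) next
        in_ring <- bonds$a1 %in% idx & bonds$a2 %in% idx
        rb <- bonds[in_ring, , drop = FALSE]
        if (nrow(rb) != 6L) next
        dbl <- rb[rb$order == 2L, , drop = FALSE]
        if (nrow(dbl) != 3L) next
        if (!setequal(c(dbl$a1, dbl$a2), idx)) next
        rings6 <- c(rings6, list(idx))
        aromatic[idx] <- TRUE
      }
      rings6 <- unique(rings6)
    }
  }

  structure(
    list(smiles = smiles,
         atoms = data.frame(idx = seq_len(n), element = element,
                            aromatic = aromatic, n_h = as.integer(n_h)),
         bonds = bonds,
         rings6 = rings6),
    class = "molecule_graph"
  )
}

.neighbours <- function(graph, i) {
  b <- graph$bonds
  c(b$a2[b$a1 == i], b$a1[b$a2 == i])
}

.bond_orders_of <- function(graph, i) {
  b <- graph$bonds
  c(b$order[b$a1 == i], b$order[b$a2 == i])
}

# TRUE if atom i is an sp3 carbon (all single bonds, not aromatic)
.is_sp3_carbon <- function(graph, i) {
  graph$atoms$element[i] == "C" && !graph$atoms$aromatic[i] &&
    all(.bond_orders_of(graph, i) == 1L)
}

#' Assign a SMARTS-like environment code to every heavy atom
#'
#' Each heavy atom receives exactly one code describing the atom and its
#' directly bonded neighbours (e.g. `"[CX4H2;Cl]"` for a CH2 bonded to
#' chlorine, whose donor sites are polarised to alpha = 1.6). Codes are
#' determined purely by the local environment, so they are invariant to
#' atom numbering and to the SMILES writing order. Environments without a
#' calibrated template raise an error naming the environment.
#'
#' @param graph A [parse_structure()] result.
#' @return Character vector of group codes, one per heavy atom, in atom
#'   order.
#' @examples
#' assign_atom_codes(parse_structure("CCO")) # CH3, CH2, alcohol OH
#' @export
assign_atom_codes <- function(graph) {
  stopifnot(inherits(graph, "molecule_graph"))
  at <- graph$atoms
  vapply(seq_len(nrow(at)), function(i) {
    el <- at$element[i]
    nh <- at$n_h[i]
    nb <- .neighbours(graph, i)
    orders <- .bond_orders_of(graph, i)
    nb_el <- at$element[nb]

    fail <- function(why) {
      stop("no registered SSIP template for atom ", i, " (", el, ", ", nh,
           " H) in '", graph$smiles, "': ", why, call. = FALSE)
    }

    if (el == "C") {
      if (at$aromatic[i]) {
        if (nh >= 1L) return("[cH]")
        ring_nb <- nb[at$aromatic[nb]]
        ext <- nb[!at$aromatic[nb]]
        if (length(ring_nb) > 2L) fail("fused aromatic carbon")
        if (length(ext) == 1L && .is_sp3_carbon(graph, ext)) {
          return("[c;alkyl]")
        }
        fail("aromatic carbon with a non-alkyl substituent")
      }
      if (length(orders) == 0L || all(orders == 1L)) {
        code <- paste0("[CX4H", nh, "]")
        if (nh >= 1L && any(nb_el == "Cl")) code <- paste0("[CX4H", nh, ";Cl]")
        return(code)
      }
      if (sum(orders == 2L) == 1L && !any(orders >= 3L)) {
        dbl_partner <- nb[which(orders == 2L)]
        if (at$element[dbl_partner] == "O") {
          others <- setdiff(nb, dbl_partner)
          if (nh == 0L && all(at$element[others] == "C")) {
            return("[CX3H0;=O]")
          }
          fail("carbonyl carbon outside the ketone template")
        }
        if (any(nb_el %in% c("N", "S"))) fail("heterosubstituted sp2 carbon")
        return(paste0("[CX3H", nh, "]"))
      }
      if (any(orders == 3L) || sum(orders == 2L) == 2L) return("[CX2]")
      fail("unrecognised carbon hybridisation")
    }

    if (el == "O") {
      if (any(orders == 2L)) {
        partner <- nb[which(orders == 2L)[1]]
        if (at$element[partner] == "C") return("[OX1;=C]")
        fail("O double-bonded to a non-carbon atom")
      }
      if (nh == 2L) return("[OX2H2]")
      if (nh == 1L) {
        if (length(nb) == 1L && .is_sp3_carbon(graph, nb)) return("[OX2H1]")
        fail("hydroxyl outside the aliphatic alcohol template")
      }
      if (all(vapply(nb, function(j) .is_sp3_carbon(graph, j), logical(1)))) {
        return("[OX2H0]")
      }
      fail("ether oxygen outside the dialkyl ether template")
    }

    if (el == "N") {
      if (any(orders == 3L) && length(nb) == 1L) return("[NX1]")
      fail("nitrogen environment outside the nitrile template")
    }

    if (el == "Cl") {
      if (length(nb) == 1L && .is_sp3_carbon(graph, nb)) return("[Cl;C]")
      fail("chlorine not bonded to an sp3 carbon")
    }

    fail("element without calibrated functional-group parameters")
  }, character(1))
}
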