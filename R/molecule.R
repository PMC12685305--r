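# Heavy-atom molecular graphs. Hydrogens are implicit throughout: only
# heavy atoms appear as nodes; implicit H counts are derived from
# standard valences (charge-adjusted).

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

# standard valence states, tried smallest-first when assigning implicit H
STANDARD_VALENCES <- list(
  B = 3, C = 4, N = 3, O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1
)

ATOMIC_MASS <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999,
  F = 18.998, P = 30.974, S = 32.06, Cl = 35.453, Br = 79.904, I = 126.904
)

#' Construct a molecule (heavy-atom chemical graph)
#'
#' @param atoms data.frame with columns `element` (symbol), `charge`
#'   (integer formal charge) and `aromatic` (logical). An optional
#'   `h_explicit` column carries bracket-atom hydrogen counts (NA where
#'   implicit rules apply).
#' @param bonds data.frame with columns `i`, `j` (1-based atom indices)
#'   and `order` (1, 2, 3, or 1.5 for aromatic bonds).
#' @param coords optional n x 3 numeric matrix of 3D coordinates (angstrom).
#' @param id text label.
#' @param validate run the structural/valence validator (default TRUE).
#' @return an object of class `molecule`.
#' @export
molecule <- function(atoms, bonds, coords = NULL, id = "", validate = TRUE) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (is.null(atoms$charge)) atoms$charge <- 0L
  if (is.null(atoms$aromatic)) atoms$aromatic <- FALSE
  if (is.null(atoms$h_explicit)) atoms$h_explicit <- NA_integer_
  atoms$charge <- as.integer(atoms$charge)
  atoms$aromatic <- as.logical(atoms$aromatic)
  if (is.null(bonds) || NROW(bonds) == 0L) {
    bonds <- data.frame(i = integer(), j = integer(), order = numeric())
  } else {
    bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
    bonds$i <- as.integer(bonds$i); bonds$j <- as.integer(bonds$j)
    bonds$order <- as.numeric(bonds$order)
    swap <- bonds$i > bonds$j
    tmp <- bonds$i[swap]; bonds$i[swap] <- bonds$j[swap]; bonds$j[swap] <- tmp
  }
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    storage.mode(coords) <- "double"
  }
  mol <- structure(list(atoms = atoms, bonds = bonds, coords = coords, id = id),
                   class = "molecule")
  if (validate) validate_molecule(mol)
  mol
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule%s: %d heavy atoms, %d bonds%s>\n",
              if (nzchar(x$id)) paste0(" ", x$id) else "",
              n_atoms(x), nrow(x$bonds),
              if (!is.null(x$coords)) ", 3D" else ""))
  invisible(x)
}

#' Number of heavy atoms
#' @param mol a molecule
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

#' Validate molecule structural invariants
#'
#' Checks bond indices, self-loops, duplicate bonds, coordinate shape and
#' valence (implicit hydrogens must be assignable). Valence violations
#' report the offending atom index.
#' @param mol a molecule
#' @return invisibly TRUE, or an error
#' @export
validate_molecule <- function(mol) {
  n <- n_atoms(mol)
  b <- mol$bonds
  if (n == 0L) abort2("molecule has no atoms", "cavigrow_parse_error")
  if (nrow(b)) {
    if (any(b$i < 1L | b$j > n))
      abort2("bond references a non-existent atom", "cavigrow_parse_error")
    if (any(b$i == b$j))
      abort2("self-loop bond", "cavigrow_parse_error")
    key <- paste(b$i, b$j)
    if (anyDuplicated(key))
      abort2("duplicate bond", "cavigrow_parse_error")
    if (!all(b$order %in% c(1, 2, 3, 1.5)))
      abort2("bond order must be 1, 2, 3 or aromatic (1.5)", "cavigrow_parse_error")
  }
  if (!is.null(mol$coords) &&
      (nrow(mol$coords) != n || ncol(mol$coords) != 3L))
    abort2("coords3d must be one (x,y,z) triple per atom", "cavigrow_parse_error")
  implicit_hydrogens(mol)  # errors on valence violation
  invisible(TRUE)
}

#' Adjacency list of the heavy-atom graph
#' @param mol a molecule
#' @return list of integer neighbor vectors
#' @export
adjacency <- function(mol) {
  n <- n_atoms(mol)
  adj <- vector("list", n)
  for (k in seq_len(n)) adj[[k]] <- integer()
  b <- mol$bonds
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      adj[[b$i[k]]] <- c(adj[[b$i[k]]], b$j[k])
      adj[[b$j[k]]] <- c(adj[[b$j[k]]], b$i[k])
    }
  }
  adj
}

# sum of bond orders incident to each atom (aromatic = 1.5)
bond_order_sums <- function(mol) {
  n <- n_atoms(mol)
  s <- numeric(n)
  b <- mol$bonds
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      s[b$i[k]] <- s[b$i[k]] + b$order[k]
      s[b$j[k]] <- s[b$j[k]] + b$order[k]
    }
  }
  s
}

# valence actually consumed per atom: like bond_order_sums, but aromatic
# bonds at aromatic O/S count 1 (the heteroatom donates a lone pair to
# the ring, not a pi electron from a double bond)
valence_used <- function(mol) {
  n <- n_atoms(mol)
  s <- numeric(n)
  b <- mol$bonds
  lone_pair <- mol$atoms$element %in% c("O", "S") & mol$atoms$aromatic
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      o <- b$order[k]
      s[b$i[k]] <- s[b$i[k]] + if (o == 1.5 && lone_pair[b$i[k]]) 1 else o
      s[b$j[k]] <- s[b$j[k]] + if (o == 1.5 && lone_pair[b$j[k]]) 1 else o
    }
  }
  s
}

#' Implicit hydrogen count per heavy atom
#'
#' The smallest standard valence state (charge-adjusted for N/O/S/P) that
#' accommodates the summed bond orders determines the hydrogen count.
#' Aromatic bond-order sums are floored (a fused aromatic carbon with
#' three ring bonds sums to 4.5 and still carries no H). Bracket-atom
#' explicit H counts override the rule. A valence that cannot be
#' satisfied raises an error naming the atom index.
#'
#' @param mol a molecule
#' @return integer vector of hydrogen counts
#' @export
implicit_hydrogens <- function(mol) {
  used <- floor(valence_used(mol) + 1e-9)
  n <- n_atoms(mol)
  h <- integer(n)
  for (k in seq_len(n)) {
    if (!is.na(mol$atoms$h_explicit[k])) {
      h[k] <- mol$atoms$h_explicit[k]
      next
    }
    el <- mol$atoms$element[k]
    std <- STANDARD_VALENCES[[el]]
    if (is.null(std)) { h[k] <- 0L; next }  # exotic element: no implicit H
    chg <- mol$atoms$charge[k]
    # charge raises N valence (+1 -> 4), lowers O (-1 -> 1), etc.
    allowed <- std + chg
    allowed <- allowed[allowed >= 0]
    fit <- allowed[allowed >= used[k]]
    if (!length(fit)) {
      abort2(sprintf("valence violation at atom %d (%s: %g bonds used)",
                     k, el, used[k]),
             "cavigrow_valence_error")
    }
    h[k] <- as.integer(min(fit) - used[k])
  }
  h
}

#' Heavy-atom degree of each atom
#' @param mol a molecule
#' @export
atom_degree <- function(mol) {
  n <- n_atoms(mol)
  d <- integer(n)
  b <- mol$bonds
  if (nrow(b)) {
    t1 <- tabulate(b$i, n); t2 <- tabulate(b$j, n)
    d <- t1 + t2
  }
  d
}

#' Connected components of the heavy-atom graph
#' @param mol a molecule
#' @return integer component label per atom
#' @export
mol_components <- function(mol) {
  n <- n_atoms(mol)
  adj <- adjacency(mol)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    frontier <- s
    comp[s] <- cur
    while (length(frontier)) {
      nb <- unique(unlist(adj[frontier]))
      nb <- nb[comp[nb] == 0L]
      comp[nb] <- cur
      frontier <- nb
    }
  }
  comp
}

#' All-pairs topological distances (BFS), capped
#' @param mol a molecule
#' @param cap maximum distance recorded (farther pairs get cap + 1)
#' @return integer matrix of graph distances
#' @export
topo_distances <- function(mol, cap = 30L) {
  n <- n_atoms(mol)
  adj <- adjacency(mol)
  D <- matrix(cap + 1L, n, n)
  diag(D) <- 0L
  for (s in seq_len(n)) {
    frontier <- s
    d <- 0L
    while (length(frontier) && d < cap) {
      d <- d + 1L
      nb <- unique(unlist(adj[frontier]))
      nb <- nb[D[s, nb] > d]
      if (!length(nb)) break
      D[s, nb] <- d
      frontier <- nb
    }
  }
  D
}

# --- ring perception -------------------------------------------------------

#' Ring membership of bonds and atoms
#'
#' A bond is in a ring iff it is not a bridge (Tarjan low-link). Returns
#' logical vectors for bonds and atoms plus the cycle rank.
#' @param mol a molecule
#' @return list(bond_in_ring, atom_in_ring, cycle_rank)
#' @export
ring_info <- function(mol) {
  n <- n_atoms(mol)
  b <- mol$bonds
  m <- nrow(b)
  bond_in_ring <- rep(FALSE, m)
  if (m) {
    # iterative bridge-finding DFS
    adj_e <- vector("list", n)   # (neighbor, bond index) pairs
    for (k in seq_len(n)) adj_e[[k]] <- list()
    for (k in seq_len(m)) {
      adj_e[[b$i[k]]][[length(adj_e[[b$i[k]]]) + 1L]] <- c(b$j[k], k)
      adj_e[[b$j[k]]][[length(adj_e[[b$j[k]]]) + 1L]] <- c(b$i[k], k)
    }
    disc <- integer(n); low <- integer(n); timer <- 0L
    is_bridge <- rep(FALSE, m)
    for (root in seq_len(n)) {
      if (disc[root] != 0L) next
      stack <- list(list(v = root, pe = 0L, ei = 1L))
      timer <- timer + 1L; disc[root] <- low[root] <- timer
      while (length(stack)) {
        fr <- stack[[length(stack)]]
        v <- fr$v
        if (fr$ei <= length(adj_e[[v]])) {
          edge <- adj_e[[v]][[fr$ei]]
          stack[[length(stack)]]$ei <- fr$ei + 1L
          u <- edge[1]; eidx <- edge[2]
          if (eidx == fr$pe) next
          if (disc[u] == 0L) {
            timer <- timer + 1L; disc[u] <- low[u] <- timer
            stack[[length(stack) + 1L]] <- list(v = u, pe = eidx, ei = 1L)
          } else {
            low[v] <- min(low[v], disc[u])
          }
        } else {
          stack[[length(stack)]] <- NULL
          if (length(stack)) {
            p <- stack[[length(stack)]]$v
            low[p] <- min(low[p], low[v])
            if (low[v] > disc[p]) is_bridge[fr$pe] <- TRUE
          }
        }
      }
    }
    bond_in_ring <- !is_bridge
  }
  atom_in_ring <- rep(FALSE, n)
  if (any(bond_in_ring)) {
    atom_in_ring[unique(c(b$i[bond_in_ring], b$j[bond_in_ring]))] <- TRUE
  }
  ncomp <- max(mol_components(mol))
  list(bond_in_ring = bond_in_ring, atom_in_ring = atom_in_ring,
       cycle_rank = m - n + ncomp)
}

#' Smallest rings through each ring bond
#'
#' For every ring bond, the shortest cycle through it is recovered by BFS
#' with the bond removed; rings are deduplicated by atom set. An SSSR-like
#' ring set adequate for ring-count and aromatic-ring descriptors.
#' @param mol a molecule
#' @return list of integer atom-index vectors (one per ring)
#' @export
find_rings <- function(mol) {
  ri <- ring_info(mol)
  b <- mol$bonds
  adj <- adjacency(mol)
  rings <- list()
  seen <- character()
  for (k in which(ri$bond_in_ring)) {
    src <- b$i[k]; dst <- b$j[k]
    # BFS src -> dst avoiding bond k
    n <- n_atoms(mol)
    prev <- integer(n); prev[src] <- -1L
    frontier <- src
    found <- FALSE
    while (length(frontier) && !found) {
      nxt <- integer()
      for (v in frontier) {
        for (u in adj[[v]]) {
          if (v == src && u == dst) next
          if (v == dst && u == src) next
          if (prev[u] == 0L) {
            prev[u] <- v
            if (u == dst) { found <- TRUE; break }
            nxt <- c(nxt, u)
          }
        }
        if (found) break
      }
      frontier <- nxt
    }
    if (!found) next
    path <- dst
    v <- dst
    while (prev[v] != -1L) { v <- prev[v]; path <- c(path, v) }
    key <- paste(sort(path), collapse = ",")
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      rings[[length(rings) + 1L]] <- path
    }
  }
  rings
}

#' Perceive aromaticity from a kekulized graph
#'
#' Marks as aromatic: 6-membered rings carrying three alternating ring
#' double bonds (benzene/pyridine pattern) and 5-membered rings with two
#' ring double bonds plus one N/O/S lone-pair donor (pyrrole/furan/
#' thiophene/imidazole pattern). Atoms already flagged aromatic are left
#' untouched. Covers the aromatic systems the fragment library and the
#' parsers emit; exotic aromaticity is out of scope.
#'
#' @param mol a molecule
#' @return the molecule with aromatic flags and ring bonds set to 1.5
#' @export
perceive_aromaticity <- function(mol) {
  rings <- find_rings(mol)
  if (!length(rings)) return(mol)
  b <- mol$bonds
  bond_idx <- function(i, j) {
    which((b$i == min(i, j)) & (b$j == max(i, j)))
  }
  for (ring in rings) {
    sz <- length(ring)
    if (!(sz %in% c(5L, 6L))) next
    # bonds around the ring, in order
    ringb <- integer(sz)
    ok <- TRUE
    for (t in seq_len(sz)) {
      idx <- bond_idx(ring[t], ring[(t %% sz) + 1L])
      if (!length(idx)) { ok <- FALSE; break }
      ringb[t] <- idx
    }
    if (!ok) next
    orders <- b$order[ringb]
    ndouble <- sum(orders == 2)
    aromatic <- FALSE
    if (sz == 6L && (ndouble == 3L || all(orders == 1.5))) {
      # alternating pattern check: no two adjacent doubles
      dpos <- which(orders == 2)
      if (ndouble == 3L) {
        gaps <- diff(c(dpos, dpos[1] + sz))
        aromatic <- all(gaps == 2L)
      } else aromatic <- TRUE
    } else if (sz == 5L) {
      hetero <- mol$atoms$element[ring] %in% c("N", "O", "S")
      if ((ndouble == 2L && any(hetero)) || all(orders == 1.5)) {
        # lone-pair donor must sit between the two double bonds
        aromatic <- TRUE
      }
    }
    if (aromatic) {
      mol$atoms$aromatic[ring] <- TRUE
      mol$bonds$order[ringb] <- 1.5
      b <- mol$bonds
    }
  }
  mol
}

#' Exact molecular weight including implicit hydrogens
#' @param mol a molecule
#' @export
mol_weight <- function(mol) {
  h <- implicit_hydrogens(mol)
  m <- ATOMIC_MASS[mol$atoms$element]
  m[is.na(m)] <- 0
  sum(m) + sum(h) * ATOMIC_MASS[["H"]]
}
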