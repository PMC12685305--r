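# SMILES line-notation I/O over the subset the pipeline needs: organic
# subset + bracket atoms, ring-closure digits (incl. %nn), branches,
# aromatic lowercase atoms, charges and explicit bracket hydrogens.
# Stereochemistry and isotopes are accepted and discarded (non-goals).

#' Parse a SMILES string into a molecule
#'
#' @param smi SMILES string.
#' @param id optional molecule label.
#' @return a `molecule`
#' @export
parse_smiles <- function(smi, id = "") {
  if (!is.character(smi) || length(smi) != 1L || !nzchar(trimws(smi)))
    abort2("empty SMILES string", "cavigrow_parse_error")
  s <- trimws(smi)
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)

  elements <- character(); charges <- integer(); aromatics <- logical()
  h_explicit <- integer()
  bi <- integer(); bj <- integer(); bord <- numeric()

  prev_stack <- integer()   # branch stack
  prev <- 0L                # last atom index
  pending <- NA_real_       # pending explicit bond order
  ring_open <- list()       # closure label -> c(atom, order)

  add_atom <- function(el, arom, chg, hx) {
    elements[length(elements) + 1L] <<- el
    aromatics[length(aromatics) + 1L] <<- arom
    charges[length(charges) + 1L] <<- chg
    h_explicit[length(h_explicit) + 1L] <<- hx
    idx <- length(elements)
    if (prev > 0L) {
      ord <- pending
      if (is.na(ord)) ord <- if (arom && aromatics[prev]) 1.5 else 1
      bi[length(bi) + 1L] <<- prev; bj[length(bj) + 1L] <<- idx
      bord[length(bord) + 1L] <<- ord
    }
    pending <<- NA_real_
    prev <<- idx
    idx
  }

  close_ring <- function(lab) {
    if (prev == 0L)
      abort2(sprintf("ring closure %s before any atom", lab), "cavigrow_parse_error")
    if (!is.null(ring_open[[lab]])) {
      op <- ring_open[[lab]]
      ord <- pending
      if (is.na(ord)) ord <- op[2]
      if (is.na(ord)) {
        ord <- if (aromatics[prev] && aromatics[op[1]]) 1.5 else 1
      }
      bi[length(bi) + 1L] <<- op[1]; bj[length(bj) + 1L] <<- prev
      bord[length(bord) + 1L] <<- ord
      ring_open[[lab]] <<- NULL
    } else {
      ring_open[[lab]] <<- c(prev, pending)
    }
    pending <<- NA_real_
  }

  k <- 1L
  while (k <= n) {
    ch <- chars[k]
    if (ch == "[") {
      close_pos <- k
      while (close_pos <= n && chars[close_pos] != "]") close_pos <- close_pos + 1L
      if (close_pos > n) abort2("unclosed bracket atom", "cavigrow_parse_error")
      inner <- substr(s, k + 1L, close_pos - 1L)
      m <- regmatches(inner, regexec(
        "^([0-9]*)([A-Za-z][a-z]?)(@{0,2})(H([0-9]*))?([+-]+[0-9]*)?(:[0-9]+)?$",
        inner))[[1]]
      if (!length(m))
        abort2(sprintf("cannot parse bracket atom [%s]", inner), "cavigrow_parse_error")
      sym <- m[3]
      arom <- sym == tolower(sym) && sym %in% c("b", "c", "n", "o", "p", "s")
      el <- if (arom) paste0(toupper(substr(sym, 1, 1)), substring(sym, 2)) else sym
      hx <- if (nzchar(m[5])) { if (nzchar(m[6])) as.integer(m[6]) else 1L } else 0L
      chg <- 0L
      if (nzchar(m[7])) {
        cs <- m[7]
        num <- suppressWarnings(as.integer(gsub("[+-]", "", cs)))
        sign <- if (substr(cs, 1, 1) == "+") 1L else -1L
        chg <- if (!is.na(num)) sign * num else sign * nchar(cs)
      }
      add_atom(el, arom, chg, hx)
      k <- close_pos + 1L
    } else if (ch %in% c("C", "B") && k < n && chars[k + 1L] %in% c("l", "r") &&
               paste0(ch, chars[k + 1L]) %in% c("Cl", "Br")) {
      add_atom(paste0(ch, chars[k + 1L]), FALSE, 0L, NA_integer_)
      k <- k + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      add_atom(ch, FALSE, 0L, NA_integer_)
      k <- k + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      add_atom(toupper(ch), TRUE, 0L, NA_integer_)
      k <- k + 1L
    } else if (ch == "-") { pending <- 1; k <- k + 1L
    } else if (ch == "=") { pending <- 2; k <- k + 1L
    } else if (ch == "#") { pending <- 3; k <- k + 1L
    } else if (ch == ":") { pending <- 1.5; k <- k + 1L
    } else if (ch %in% c("/", "\\")) { pending <- 1; k <- k + 1L  # stereo dropped
    } else if (ch == "(") {
      if (prev == 0L) abort2("branch before any atom", "cavigrow_parse_error")
      prev_stack <- c(prev_stack, prev); k <- k + 1L
    } else if (ch == ")") {
      if (!length(prev_stack)) abort2("unbalanced ')'", "cavigrow_parse_error")
      prev <- prev_stack[length(prev_stack)]
      prev_stack <- prev_stack[-length(prev_stack)]
      k <- k + 1L
    } else if (grepl("[0-9]", ch)) {
      close_ring(ch); k <- k + 1L
    } else if (ch == "%") {
      if (k + 2L > n) abort2("truncated %nn ring label", "cavigrow_parse_error")
      close_ring(paste0(chars[k + 1L], chars[k + 2L])); k <- k + 3L
    } else if (ch == ".") {
      prev <- 0L; pending <- NA_real_; k <- k + 1L
    } else {
      abort2(sprintf("unexpected character '%s' at position %d", ch, k),
             "cavigrow_parse_error")
    }
  }
  if (length(ring_open))
    abort2("unclosed ring bond", "cavigrow_parse_error")
  if (!length(elements))
    abort2("SMILES contains no atoms", "cavigrow_parse_error")

  mol <- molecule(
    atoms = data.frame(element = elements, charge = charges,
                       aromatic = aromatics, h_explicit = h_explicit,
                       stringsAsFactors = FALSE),
    bonds = data.frame(i = bi, j = bj, order = bord),
    id = id, validate = FALSE)
  mol <- perceive_aromaticity(mol)
  validate_molecule(mol)
  mol
}

# implicit H a parser would infer for a plain (non-bracket) atom token
infer_plain_h <- function(el, arom, used) {
  std <- STANDARD_VALENCES[[el]]
  if (is.null(std)) return(NA_integer_)
  u <- floor(used + 1e-9)
  fit <- std[std >= u]
  if (!length(fit)) return(NA_integer_)
  as.integer(min(fit) - u)
}

#' Write a molecule as a SMILES string
#'
#' Atoms are emitted in DFS order following `ranks` (lower rank first);
#' with canonical ranks this yields the canonical form. A first DFS pass
#' fixes the spanning tree and ring-closure labels; the second emits.
#'
#' @param mol a molecule
#' @param ranks optional integer ordering key per atom (default input order)
#' @return SMILES string
#' @export
write_smiles <- function(mol, ranks = NULL) {
  n <- n_atoms(mol)
  if (is.null(ranks)) ranks <- seq_len(n)
  adj <- adjacency(mol)
  b <- mol$bonds
  bmat_key <- paste(b$i, b$j)
  order_of <- function(i, j) b$order[match(paste(min(i, j), max(i, j)), bmat_key)]
  hcounts <- implicit_hydrogens(mol)

  bond_sym <- function(ord, ai, aj) {
    if (ord == 2) return("=")
    if (ord == 3) return("#")
    if (ord == 1.5) {
      if (mol$atoms$aromatic[ai] && mol$atoms$aromatic[aj]) return("")
      return(":")
    }
    # explicit single between two aromatic atoms (biphenyl case)
    if (mol$atoms$aromatic[ai] && mol$atoms$aromatic[aj]) return("-")
    ""
  }

  atom_token <- function(k) {
    el <- mol$atoms$element[k]
    arom <- mol$atoms$aromatic[k]
    sym <- if (arom) tolower(el) else el
    chg <- mol$atoms$charge[k]
    used <- valence_used(mol)[k]
    if (el %in% ORGANIC_SUBSET && chg == 0L) {
      hinf <- infer_plain_h(el, arom, used)
      if (!is.na(hinf) && hinf == hcounts[k]) return(sym)
    }
    hc <- hcounts[k]
    hstr <- if (hc == 0L) "" else if (hc == 1L) "H" else paste0("H", hc)
    cstr <- if (chg == 0L) "" else if (chg == 1L) "+" else if (chg == -1L) "-"
      else if (chg > 0L) paste0("+", chg) else paste0("-", abs(chg))
    paste0("[", sym, hstr, cstr, "]")
  }

  # --- pass 1: DFS spanning forest + ring-closure labels -------------------
  visited <- rep(FALSE, n)
  children <- vector("list", n)
  ring_at <- vector("list", n)   # atom -> list of c(label, order, partner, open)
  ring_counter <- 0L
  roots <- integer()

  comp <- mol_components(mol)
  for (cc in sort(unique(comp))) {
    members <- which(comp == cc)
    root <- members[which.min(ranks[members])]
    roots <- c(roots, root)
    visited[root] <- TRUE
    walk <- function(k, parent) {
      nbrs <- adj[[k]]
      nbrs <- nbrs[order(ranks[nbrs])]
      for (u in nbrs) {
        if (u == parent) next
        if (visited[u]) {
          # back edge to an ancestor: one ring-closure label per edge
          already <- any(vapply(ring_at[[k]], function(r) r[3] == u, logical(1)))
          if (!already) {
            ring_counter <<- ring_counter + 1L
            lab <- ring_counter
            ord <- order_of(k, u)
            ring_at[[u]] <<- c(ring_at[[u]], list(c(lab, ord, k, 1L)))
            ring_at[[k]] <<- c(ring_at[[k]], list(c(lab, ord, u, 0L)))
          }
        } else {
          visited[u] <<- TRUE
          children[[k]] <<- c(children[[k]], u)
          walk(u, k)
        }
      }
    }
    walk(root, 0L)
  }

  # --- pass 2: emit --------------------------------------------------------
  lab_str <- function(lab) if (lab > 9L) sprintf("%%%02d", lab) else as.character(lab)
  emit <- function(k) {
    res <- atom_token(k)
    for (rc in ring_at[[k]]) {
      sym <- if (rc[4] == 1L) "" else bond_sym(rc[2], k, rc[3])
      res <- paste0(res, sym, lab_str(rc[1]))
    }
    ch <- children[[k]]
    if (length(ch)) {
      parts <- vapply(ch, function(u) {
        paste0(bond_sym(order_of(k, u), k, u), emit(u))
      }, character(1))
      if (length(parts) > 1L) {
        res <- paste0(res,
                      paste0("(", parts[-length(parts)], ")", collapse = ""),
                      parts[length(parts)])
      } else {
        res <- paste0(res, parts[1])
      }
    }
    res
  }

  paste(vapply(roots, emit, character(1)), collapse = ".")
}

#' Read a SMILES file (one record per line, optional whitespace-separated id)
#'
#' Unparsable lines are skipped with a warning; an error is raised if more
#' than half the non-empty lines fail.
#'
#' @param path file path
#' @return list of molecules
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) abort2("no SMILES records in file", "cavigrow_io_error")
  mols <- list(); nfail <- 0L
  for (ln in lines) {
    parts <- strsplit(ln, "[ \t]+")[[1]]
    id <- if (length(parts) > 1L) parts[2] else ""
    m <- tryCatch(parse_smiles(parts[1], id = id), error = function(e) NULL)
    if (is.null(m)) { nfail <- nfail + 1L; next }
    mols[[length(mols) + 1L]] <- m
  }
  if (nfail > 0L)
    warning(sprintf("%d of %d SMILES records could not be parsed",
                    nfail, length(lines)))
  if (nfail > length(lines) / 2)
    abort2("more than half of the SMILES records are unparsable",
           "cavigrow_io_error")
  mols
}

#' Write molecules to a SMILES file
#' @param mols list of molecules
#' @param path output path
#' @param canonical write canonical forms (default TRUE)
#' @export
write_smiles_file <- function(mols, path, canonical = TRUE) {
  lines <- vapply(mols, function(m) {
    smi <- if (canonical) canonicalize(m) else write_smiles(m)
    if (nzchar(m$id)) paste(smi, m$id) else smi
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
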