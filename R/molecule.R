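# Heavy-atom molecular graphs parsed from SMILES.
#
# The descriptor pipeline needs three things per molecule: the element /
# charge / aromaticity of every heavy atom, implicit hydrogen counts, and
# all-pairs topological (bond-count) distances. A Daylight-style SMILES
# subset (organic-subset atoms, bracket atoms with charge and H counts,
# ring closures, branches, aromatic lowercase) carries exactly that; 3-D
# information and stereochemistry are parsed but discarded because all
# descriptors here are 2-D.

# default valences used for implicit-H assignment; multivalent elements
# take the smallest valence that accommodates the explicit bond sum
.VALENCES <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1
)
.ORGANIC_SUBSET <- names(.VALENCES)
.AROMATIC_ELEMS <- c("B", "C", "N", "O", "P", "S")

#' Parse a SMILES string into a heavy-atom molecular graph
#'
#' Parses a Daylight-style SMILES subset: organic-subset atoms
#' (`B C N O P S F Cl Br I`), aromatic lowercase (`b c n o p s`), bracket
#' atoms with isotope, charge, chirality and explicit H counts, bond symbols
#' (`- = # : / \`), ring closures (digits and `%nn`) and branches.
#' Stereochemistry and isotopes are accepted and ignored. Disconnected
#' SMILES (salts, mixtures) are reduced to the largest connected component.
#'
#' Implicit hydrogens follow standard valence rules (bracket atoms carry
#' exactly their stated H count); a default bond between two aromatic atoms
#' is aromatic when it lies in a ring and single otherwise (the biphenyl
#' rule), and every atom written lowercase must end up in an aromatic ring.
#'
#' @param smiles A single SMILES string.
#' @param id Identifier used in the returned molecule and in error messages.
#' @return An object of class `molecule`: a list with `id`; `atoms`
#'   (data.frame of `element`, `charge`, `aromatic`, `implicit_h`); `bonds`
#'   (data.frame of `a1`, `a2`, `order` with 1, 2, 3 or 1.5 for aromatic);
#'   and `topo_dist`, the symmetric matrix of shortest-path bond counts.
#' @examples
#' m <- parse_smiles("CCO", id = "ethanol")
#' m$atoms$implicit_h          # 3 2 1
#' m$topo_dist["a1", "a3"]     # 2 bonds from terminal C to O
#' @export
parse_smiles <- function(smiles, id = smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    stop("parse error [", id, "]: SMILES must be a non-empty string",
         call. = FALSE)
  }
  perr <- function(...) {
    stop("parse error [", id, "]: ", ..., call. = FALSE)
  }

  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  i <- 1L

  elem <- character(0); charge <- integer(0); arom <- logical(0)
  h_spec <- rep(NA_integer_, 0)
  b_a1 <- integer(0); b_a2 <- integer(0); b_sym <- character(0)

  prev <- 0L
  pending <- ""             # bond symbol awaiting the next atom/ring digit
  branch_stack <- integer(0)
  rings <- list()           # open ring closures: key -> c(atom, sym)

  add_atom <- function(el, ar, ch = 0L, h = NA_integer_) {
    elem[length(elem) + 1L] <<- el
    charge[length(charge) + 1L] <<- ch
    arom[length(arom) + 1L] <<- ar
    h_spec[length(h_spec) + 1L] <<- h
    idx <- length(elem)
    if (prev > 0L) {
      b_a1[length(b_a1) + 1L] <<- prev
      b_a2[length(b_a2) + 1L] <<- idx
      b_sym[length(b_sym) + 1L] <<- pending
    } else if (nzchar(pending)) {
      perr("bond symbol with no preceding atom")
    }
    pending <<- ""
    prev <<- idx
    invisible(idx)
  }

  close_ring <- function(key) {
    sym <- pending; pending <<- ""
    if (prev == 0L) perr("ring closure before any atom")
    if (is.null(rings[[key]])) {
      rings[[key]] <<- list(atom = prev, sym = sym)
    } else {
      open <- rings[[key]]
      use <- open$sym
      if (nzchar(sym)) {
        if (nzchar(use) && use != sym)
          perr("conflicting bond symbols on ring closure ", key)
        use <- sym
      }
      if (open$atom == prev) perr("ring closure bonds an atom to itself")
      b_a1[length(b_a1) + 1L] <<- open$atom
      b_a2[length(b_a2) + 1L] <<- prev
      b_sym[length(b_sym) + 1L] <<- use
      rings[[key]] <<- NULL
    }
  }

  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) perr("unterminated bracket atom")
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      at <- .parse_bracket(body, perr)
      add_atom(at$elem, at$aromatic, at$charge, at$h)
      i <- j + 1L
    } else if (i < n && paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      add_atom(paste0(ch, chars[i + 1L]), FALSE)
      i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      add_atom(ch, FALSE)
      i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      add_atom(toupper(ch), TRUE)
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":")) {
      if (nzchar(pending)) perr("two consecutive bond symbols")
      pending <- ch
      i <- i + 1L
    } else if (ch %in% c("/", "\\")) {
      if (nzchar(pending)) perr("two consecutive bond symbols")
      pending <- "-"   # cis/trans marks are single bonds; geometry ignored
      i <- i + 1L
    } else if (ch == "(") {
      if (prev == 0L) perr("branch opened before any atom")
      branch_stack <- c(branch_stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(branch_stack) == 0L) perr("unmatched ')'")
      prev <- branch_stack[length(branch_stack)]
      branch_stack <- branch_stack[-length(branch_stack)]
      i <- i + 1L
    } else if (ch == ".") {
      if (nzchar(pending)) perr("bond symbol across component separator")
      prev <- 0L
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      close_ring(ch)
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$",
                               paste(chars[i + 1:2], collapse = "")))
        perr("'%' ring closure needs two digits")
      close_ring(paste(chars[i + 1:2], collapse = ""))
      i <- i + 3L
    } else {
      perr("unexpected character '", ch, "'")
    }
  }
  if (length(branch_stack) > 0L) perr("unclosed branch '('")
  if (length(rings) > 0L)
    perr("unclosed ring bond(s): ", paste(names(rings), collapse = ", "))
  if (length(elem) == 0L) perr("no atoms")
  if (nzchar(pending)) perr("dangling bond symbol")

  .build_molecule(id, elem, charge, arom, h_spec, b_a1, b_a2, b_sym, perr)
}

# bracket-atom body, e.g. "nH+", "13CH3", "O-", "N@@H2+", "Fe" rejected
.parse_bracket <- function(body, perr) {
  rest <- body
  rest <- sub("^[0-9]+", "", rest)                      # isotope: ignored
  m <- regmatches(rest, regexpr("^([A-Z][a-z]?|[bcnops])", rest))
  if (length(m) == 0L) perr("unsupported bracket atom [", body, "]")
  sym <- m
  rest <- substring(rest, nchar(sym) + 1L)
  aromatic <- sym %in% c("b", "c", "n", "o", "p", "s")
  el <- if (aromatic) toupper(sym) else sym
  rest <- gsub("^@{1,2}", "", rest)                     # chirality: ignored
  h <- 0L
  hm <- regmatches(rest, regexpr("^H[0-9]*", rest))
  if (length(hm) == 1L) {
    h <- if (nchar(hm) == 1L) 1L else as.integer(substring(hm, 2L))
    rest <- substring(rest, nchar(hm) + 1L)
  }
  chg <- 0L
  cm <- regmatches(rest, regexpr("^(\\+[0-9]+|-[0-9]+|\\++|-+)", rest))
  if (length(cm) == 1L) {
    chg <- if (grepl("^[+-][0-9]", cm)) {
      as.integer(cm)
    } else {
      nchar(cm) * if (substring(cm, 1L, 1L) == "+") 1L else -1L
    }
    rest <- substring(rest, nchar(cm) + 1L)
  }
  rest <- sub("^:[0-9]+", "", rest)                     # atom class: ignored
  if (nzchar(rest)) perr("unsupported bracket content [", body, "]")
  list(elem = el, aromatic = aromatic, charge = chg, h = h)
}

# resolve bond orders, aromaticity and implicit H; reduce to the largest
# connected component; compute topological distances
.build_molecule <- function(id, elem, charge, arom, h_spec,
                            b_a1, b_a2, b_sym, perr) {
  n_atom <- length(elem)
  n_bond <- length(b_a1)
  if (any(b_a1 == b_a2)) perr("self-bond")

  g <- igraph::make_empty_graph(n = n_atom, directed = FALSE)
  if (n_bond > 0L) {
    g <- igraph::add_edges(g, rbind(b_a1, b_a2))
    is_bridge <- seq_len(n_bond) %in% igraph::bridges(g)
    order <- numeric(n_bond)
    for (k in seq_len(n_bond)) {
      s <- b_sym[k]
      both_arom <- arom[b_a1[k]] && arom[b_a2[k]]
      order[k] <- switch(
        s,
        "-" = 1, "=" = 2, "#" = 3,
        ":" = 1.5,
        # default bond: aromatic when both ends are aromatic and the bond
        # lies in a ring (biphenyl's inter-ring bond stays single)
        if (both_arom && !is_bridge[k]) 1.5 else 1
      )
      if (order[k] == 1.5 && !(arom[b_a1[k]] && arom[b_a2[k]]))
        perr("aromatic bond between non-aromatic atoms")
    }
  } else {
    order <- numeric(0)
  }

  # every aromatic atom must sit in an aromatic ring (>= 2 aromatic bonds)
  if (any(arom)) {
    if (!all(elem[arom] %in% .AROMATIC_ELEMS))
      perr("element cannot be aromatic")
    n_ar_bonds <- vapply(which(arom), function(a) {
      sum((b_a1 == a | b_a2 == a) & order == 1.5)
    }, numeric(1))
    if (any(n_ar_bonds < 2))
      perr("aromatic atom outside an aromatic ring")
  }

  # implicit hydrogens: bracket atoms carry their stated count; organic-
  # subset atoms get (valence - bond sum), aromatic atoms forfeit one H to
  # the delocalized system (aromatic bonds counted as single here)
  implicit_h <- integer(n_atom)
  for (a in seq_len(n_atom)) {
    if (!is.na(h_spec[a])) {
      implicit_h[a] <- h_spec[a]
      next
    }
    bs <- sum(floor(order[b_a1 == a | b_a2 == a]))  # aromatic 1.5 -> 1
    if (arom[a]) bs <- bs + 1L
    vals <- .VALENCES[[elem[a]]]
    v <- if (any(vals >= bs)) min(vals[vals >= bs]) else max(vals)
    implicit_h[a] <- max(0L, as.integer(v - bs))
  }

  # largest connected component (salt stripping); ties -> lowest atom index
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    best <- which(comp$csize == max(comp$csize))
    if (length(best) > 1L) {
      first_atom <- vapply(best, function(cc) min(which(comp$membership == cc)),
                           numeric(1))
      best <- best[which.min(first_atom)]
    }
    keep <- which(comp$membership == best)
    remap <- match(seq_len(n_atom), keep)
    sel <- b_a1 %in% keep & b_a2 %in% keep
    b_a1 <- remap[b_a1[sel]]; b_a2 <- remap[b_a2[sel]]
    order <- order[sel]
    elem <- elem[keep]; charge <- charge[keep]; arom <- arom[keep]
    implicit_h <- implicit_h[keep]
    n_atom <- length(keep)
    g <- igraph::make_empty_graph(n = n_atom, directed = FALSE)
    if (length(b_a1) > 0L) g <- igraph::add_edges(g, rbind(b_a1, b_a2))
  }

  topo <- igraph::distances(g)
  nm <- paste0("a", seq_len(n_atom))
  dimnames(topo) <- list(nm, nm)

  structure(list(
    id = id,
    atoms = data.frame(element = elem, charge = charge, aromatic = arom,
                       implicit_h = implicit_h, stringsAsFactors = FALSE),
    bonds = data.frame(a1 = b_a1, a2 = b_a2, order = order),
    topo_dist = topo
  ), class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule %s: %d atoms, %d bonds, %d aromatic>\n",
              x$id, nrow(x$atoms), nrow(x$bonds), sum(x$atoms$aromatic)))
  invisible(x)
}

#' Number of heavy atoms in a molecule
#' @param mol A `molecule`.
#' @return Integer atom count.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

#' Write a molecule back to SMILES
#'
#' Depth-first traversal from atom 1; ring-closure digits are assigned to
#' non-tree bonds. Atoms are written in the organic subset where the
#' standard valence rules would reproduce their hydrogen count, and as
#' bracket atoms (explicit H, charge) otherwise, so parsing the output
#' recovers the same labeled graph. Used by the synthetic analog generator,
#' which edits molecules as graphs.
#'
#' @param mol A `molecule`.
#' @return A single SMILES string.
#' @export
mol_to_smiles <- function(mol) {
  n <- n_atoms(mol)
  if (n == 0L) stop("empty molecule", call. = FALSE)
  bonds <- mol$bonds
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    adj[[bonds$a1[k]]] <- c(adj[[bonds$a1[k]]], k)
    adj[[bonds$a2[k]]] <- c(adj[[bonds$a2[k]]], k)
  }
  other <- function(k, a) if (bonds$a1[k] == a) bonds$a2[k] else bonds$a1[k]

  visited <- rep(FALSE, n)
  bond_used <- rep(FALSE, max(1L, nrow(bonds)))
  ring_marks <- vector("list", n)   # atom -> list of (digit, bondsym)
  next_digit <- 0L

  bond_sym <- function(k) {
    o <- bonds$order[k]
    if (o == 2) "=" else if (o == 3) "#"
    else if (o == 1 && mol$atoms$aromatic[bonds$a1[k]] &&
             mol$atoms$aromatic[bonds$a2[k]]) "-"
    else ""
  }

  # pre-walk to find ring-closure (non-tree) bonds
  parent_bond <- rep(NA_integer_, n)
  dfs_order <- integer(0)
  stack <- 1L
  visited[1L] <- TRUE
  while (length(stack) > 0L) {
    a <- stack[length(stack)]; stack <- stack[-length(stack)]
    dfs_order <- c(dfs_order, a)
    for (k in adj[[a]]) {
      b <- other(k, a)
      if (!visited[b]) {
        visited[b] <- TRUE
        parent_bond[b] <- k
        bond_used[k] <- TRUE
        stack <- c(stack, b)
      }
    }
  }
  if (!all(visited)) stop("disconnected molecule cannot be written",
                          call. = FALSE)
  ring_bonds <- which(!bond_used & seq_along(bond_used) <= nrow(bonds))
  for (k in ring_bonds) {
    next_digit <- next_digit + 1L
    dig <- if (next_digit <= 9L) as.character(next_digit) else
      sprintf("%%%02d", next_digit)
    sym <- bond_sym(k)
    ring_marks[[bonds$a1[k]]] <- c(ring_marks[[bonds$a1[k]]],
                                   list(list(dig = dig, sym = sym)))
    ring_marks[[bonds$a2[k]]] <- c(ring_marks[[bonds$a2[k]]],
                                   list(list(dig = dig, sym = "")))
  }

  atom_token <- function(a) {
    at <- mol$atoms[a, ]
    low <- if (at$aromatic) tolower(at$element) else at$element
    plain_ok <- at$charge == 0L && at$element %in% .ORGANIC_SUBSET &&
      .inferred_h(mol, a) == at$implicit_h
    if (plain_ok) return(low)
    hpart <- if (at$implicit_h == 1L) "H"
    else if (at$implicit_h > 1L) paste0("H", at$implicit_h) else ""
    cpart <- if (at$charge > 0L) {
      if (at$charge == 1L) "+" else paste0("+", at$charge)
    } else if (at$charge < 0L) {
      if (at$charge == -1L) "-" else as.character(at$charge)
    } else ""
    paste0("[", low, hpart, cpart, "]")
  }

  emit <- function(a, in_bond_sym) {
    out <- paste0(in_bond_sym, atom_token(a))
    for (rm in ring_marks[[a]]) out <- paste0(out, rm$sym, rm$dig)
    kids <- list()
    for (k in adj[[a]]) {
      b <- other(k, a)
      if (!is.na(parent_bond[b]) && parent_bond[b] == k) {
        kids <- c(kids, list(list(atom = b, sym = bond_sym(k))))
      }
    }
    if (length(kids) > 0L) {
      for (j in seq_along(kids)) {
        sub <- emit(kids[[j]]$atom, kids[[j]]$sym)
        out <- if (j < length(kids)) paste0(out, "(", sub, ")")
        else paste0(out, sub)
      }
    }
    out
  }
  emit(1L, "")
}

# hydrogen count the parser would infer for atom a written bare
.inferred_h <- function(mol, a) {
  ords <- mol$bonds$order[mol$bonds$a1 == a | mol$bonds$a2 == a]
  bs <- sum(floor(ords))
  if (mol$atoms$aromatic[a]) bs <- bs + 1L
  vals <- .VALENCES[[mol$atoms$element[a]]]
  v <- if (any(vals >= bs)) min(vals[vals >= bs]) else max(vals)
  max(0L, as.integer(v - bs))
}

#' Read a .smi file of query compounds
#'
#' One `SMILES<whitespace>ID` per line; blank lines and lines starting with
#' `#` are skipped. Missing IDs default to `mol<line number>`.
#'
#' @param path Path to the .smi file.
#' @return Named list of `molecule` objects (names are the IDs).
#' @export
read_smiles_file <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  out <- list()
  for (li in seq_along(lines)) {
    ln <- trimws(lines[li])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    parts <- strsplit(ln, "[ \t]+")[[1]]
    id <- if (length(parts) >= 2L) parts[2L] else paste0("mol", li)
    out[[id]] <- parse_smiles(parts[1L], id = id)
  }
  out
}
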