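## Molecule model, property filters, circular fingerprints, Tanimoto
## similarity and greedy diversity picking: the library-preparation stage.

ATOMIC_MASS <- c(H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
                 F = 18.998, NA. = 22.990, MG = 24.305, P = 30.974, S = 32.06,
                 CL = 35.45, K = 39.098, BR = 79.904, I = 126.904)

## default valence used for implicit hydrogens (OpenBabel-style)
default_valence <- function(element, charge) {
  el <- toupper(element)
  v <- switch(el,
              "H" = 1, "B" = 3, "C" = 4,
              "N" = 3 + charge, "P" = 3 + charge,
              "O" = 2 + charge, "S" = 2 + charge,
              "F" = 1, "CL" = 1, "BR" = 1, "I" = 1,
              NA_real_)
  if (is.na(v)) stop("unknown element: ", element)
  max(0, v)
}

#' Construct a Molecule object
#'
#' @param id compound identifier.
#' @param elements character vector of element symbols.
#' @param bonds data.frame (or 3-column matrix) of `i`, `j`, `order`; order 4
#'   denotes an aromatic bond (SD-file convention). Six-membered rings drawn
#'   with alternating single/double (Kekule) bonds are perceived as aromatic.
#' @param charges integer formal charges (default 0).
#' @param name optional free-text name.
#' @return A [Molecule-class].
#' @export
Molecule <- function(id, elements, bonds = NULL, charges = NULL, name = "") {
  if (is.null(charges)) charges <- rep(0L, length(elements))
  if (is.null(bonds) || NROW(bonds) == 0) {
    b <- data.frame(i = integer(), j = integer(), order = integer())
  } else {
    b <- as.data.frame(bonds)
    names(b) <- c("i", "j", "order")
    b$i <- as.integer(b$i); b$j <- as.integer(b$j)
    b$order <- as.integer(b$order)
  }
  m <- new("Molecule", id = as.character(id),
           atoms = data.frame(element = toupper(elements),
                              charge = as.integer(charges)),
           bonds = b, name = name)
  perceive_aromaticity(m)
}

## adjacency list: for each atom, data.frame of (neighbor, order)
mol_adjacency <- function(m) {
  n <- nrow(m@atoms)
  adj <- vector("list", n)
  for (k in seq_len(nrow(m@bonds))) {
    i <- m@bonds$i[k]; j <- m@bonds$j[k]; o <- m@bonds$order[k]
    adj[[i]] <- rbind(adj[[i]], c(j, o, k))
    adj[[j]] <- rbind(adj[[j]], c(i, o, k))
  }
  adj
}

## smallest ring through each bond (BFS excluding that bond); returns a list
## of integer atom-index rings, unique by membership
mol_rings <- function(m, max_size = 8L) {
  nb <- nrow(m@bonds)
  if (nb == 0) return(list())
  adj <- mol_adjacency(m)
  rings <- list(); seen <- character(0)
  for (k in seq_len(nb)) {
    src <- m@bonds$i[k]; dst <- m@bonds$j[k]
    ## BFS from src to dst avoiding bond k
    prev <- rep(NA_integer_, nrow(m@atoms))
    prev[src] <- 0L
    queue <- src
    found <- FALSE
    while (length(queue) && !found) {
      cur <- queue[1]; queue <- queue[-1]
      nbrs <- adj[[cur]]
      if (is.null(nbrs)) next
      for (r in seq_len(nrow(nbrs))) {
        if (nbrs[r, 3] == k) next
        nx <- nbrs[r, 1]
        if (!is.na(prev[nx])) next
        prev[nx] <- cur
        if (nx == dst) { found <- TRUE; break }
        queue <- c(queue, nx)
      }
    }
    if (!found) next
    path <- dst; cur <- dst
    while (prev[cur] != 0L) { cur <- prev[cur]; path <- c(path, cur) }
    if (length(path) > max_size) next
    key <- paste(sort(path), collapse = "-")
    if (!key %in% seen) { seen <- c(seen, key); rings <- c(rings, list(path)) }
  }
  rings
}

## flag Kekule benzene-like rings as aromatic (order 4)
perceive_aromaticity <- function(m) {
  rings <- mol_rings(m, max_size = 6L)
  if (!length(rings)) return(m)
  b <- m@bonds
  bond_idx <- function(i, j) which((b$i == i & b$j == j) | (b$i == j & b$j == i))
  for (ring in rings) {
    if (length(ring) != 6L) next
    ord <- integer(0)
    for (k in seq_along(ring)) {
      bi <- bond_idx(ring[k], ring[k %% length(ring) + 1L])
      ord <- c(ord, b$order[bi[1]])
    }
    if (all(ord == 4L)) next
    ## alternating single/double Kekule pattern
    if (sum(ord == 1L) == 3L && sum(ord == 2L) == 3L &&
        all(abs(diff(c(ord, ord[1]))) == 1L)) {
      for (k in seq_along(ring)) {
        bi <- bond_idx(ring[k], ring[k %% length(ring) + 1L])
        b$order[bi[1]] <- 4L
      }
    }
  }
  m@bonds <- b
  m
}

## per-atom bond order sum (aromatic = 1.5, rounded up per atom) and
## implicit hydrogen counts
implicit_hydrogens <- function(m) {
  n <- nrow(m@atoms)
  bsum <- numeric(n)
  for (k in seq_len(nrow(m@bonds))) {
    o <- m@bonds$order[k]
    val <- if (o == 4L) 1.5 else as.numeric(o)
    bsum[m@bonds$i[k]] <- bsum[m@bonds$i[k]] + val
    bsum[m@bonds$j[k]] <- bsum[m@bonds$j[k]] + val
  }
  vapply(seq_len(n), function(i) {
    el <- m@atoms$element[i]
    if (el %in% c("H", "D")) return(0L)
    v <- default_valence(el, m@atoms$charge[i])
    as.integer(max(0, round(v - ceiling(bsum[i]))))
  }, integer(1))
}

#' Molecular properties used by the library filter
#'
#' Molecular weight includes implicit hydrogens (standard valence model).
#' Hydrogen-bond donors are N/O/S atoms bearing at least one hydrogen
#' (explicit or implicit). Aromatic rings are smallest rings whose bonds are
#' all aromatic.
#'
#' @param m a [Molecule-class].
#' @return list with `mw` (Da), `hbd` and `aromaticRings` (integer counts).
#' @export
computeProperties <- function(m) {
  stopifnot(is(m, "Molecule"))
  el <- m@atoms$element
  mass <- ATOMIC_MASS[ifelse(el == "NA", "NA.", el)]
  if (anyNA(mass))
    stop("unknown element: ", paste(unique(el[is.na(mass)]), collapse = ", "))
  nh <- implicit_hydrogens(m)
  ## explicit hydrogens attached
  adj <- mol_adjacency(m)
  expl_h <- vapply(seq_along(el), function(i) {
    nbrs <- adj[[i]]
    if (is.null(nbrs)) 0L else sum(el[nbrs[, 1]] == "H")
  }, integer(1))
  mw <- sum(mass) + sum(nh) * ATOMIC_MASS[["H"]]
  hbd <- sum(el %in% c("N", "O", "S") & (nh + expl_h) >= 1L)
  rings <- mol_rings(m)
  b <- m@bonds
  arom <- 0L
  for (ring in rings) {
    ok <- TRUE
    for (k in seq_along(ring)) {
      i <- ring[k]; j <- ring[k %% length(ring) + 1L]
      bi <- which((b$i == i & b$j == j) | (b$i == j & b$j == i))
      if (!length(bi) || b$order[bi[1]] != 4L) { ok <- FALSE; break }
    }
    if (ok) arom <- arom + 1L
  }
  list(mw = as.numeric(mw), hbd = as.integer(hbd),
       aromaticRings = as.integer(arom))
}

#' Filter a library on molecular properties
#'
#' Keeps molecules satisfying all bounds (inclusive), preserving input order:
#' molecular mass within \[mwMin, mwMax\] Da, at least `hbdMin` hydrogen-bond
#' donors and at least `aromaticMin` aromatic rings.
#'
#' @param mols list of [Molecule-class] objects.
#' @param mwMin,mwMax molecular-weight bounds (Da); defaults 300-500.
#' @param hbdMin minimum hydrogen-bond donors (default 1).
#' @param aromaticMin minimum aromatic rings (default 1).
#' @return The surviving molecules, in input order, with a `properties`
#'   attribute holding the per-molecule property table.
#' @export
filterLibrary <- function(mols, mwMin = 300, mwMax = 500, hbdMin = 1,
                          aromaticMin = 1) {
  if (mwMin > mwMax) stop("mwMin exceeds mwMax")
  if (length(mols) == 0) return(mols)
  props <- lapply(mols, computeProperties)
  tab <- data.frame(id = vapply(mols, molId, character(1)),
                    mw = vapply(props, `[[`, numeric(1), "mw"),
                    hbd = vapply(props, `[[`, integer(1), "hbd"),
                    aromaticRings = vapply(props, `[[`, integer(1),
                                           "aromaticRings"))
  keep <- tab$mw >= mwMin & tab$mw <= mwMax & tab$hbd >= hbdMin &
    tab$aromaticRings >= aromaticMin
  out <- mols[keep]
  attr(out, "properties") <- cbind(tab, kept = keep)
  out
}

## deterministic 28-bit string hash (platform independent)
str_hash <- function(s) {
  v <- utf8ToInt(s)
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 268435456
  as.integer(h)
}

#' Circular (Morgan-style) fingerprint
#'
#' Deterministic iterative neighborhood hashing: atom environments of bond
#' radius 0..`radius` are hashed into a fixed bit space. Identical molecular
#' graphs always give identical bit sets.
#'
#' @param m a [Molecule-class].
#' @param radius neighborhood radius in bonds (default 2).
#' @param nbits size of the bit space (default 2048).
#' @return list with `bits` (sorted integer indices, 0-based) and `nbits`.
#' @export
fingerprint <- function(m, radius = 2L, nbits = 2048L) {
  stopifnot(is(m, "Molecule"))
  n <- nrow(m@atoms)
  if (n == 0) stop("empty molecule")
  adj <- mol_adjacency(m)
  nh <- implicit_hydrogens(m)
  arom_atom <- rep(FALSE, n)
  for (k in seq_len(nrow(m@bonds)))
    if (m@bonds$order[k] == 4L)
      arom_atom[c(m@bonds$i[k], m@bonds$j[k])] <- TRUE
  deg <- vapply(adj, function(x) if (is.null(x)) 0L else nrow(x), integer(1))
  inv <- vapply(seq_len(n), function(i) {
    str_hash(paste(m@atoms$element[i], deg[i], nh[i], m@atoms$charge[i],
                   arom_atom[i]))
  }, integer(1))
  all_inv <- inv
  for (r in seq_len(radius)) {
    inv <- vapply(seq_len(n), function(i) {
      nbrs <- adj[[i]]
      env <- if (is.null(nbrs)) "" else
        paste(sort(paste(nbrs[, 2], inv[nbrs[, 1]], sep = ":")),
              collapse = "|")
      str_hash(paste(r, inv[i], env))
    }, integer(1))
    all_inv <- c(all_inv, inv)
  }
  list(bits = sort(unique(all_inv %% as.integer(nbits))),
       nbits = as.integer(nbits))
}

#' Tanimoto similarity between two fingerprints
#'
#' `|A intersect B| / |A union B|`; defined as 1 when both bit sets are
#' empty.
#'
#' @param a,b fingerprints from [fingerprint()].
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  if (a$nbits != b$nbits)
    stop("fingerprint bit-space mismatch: ", a$nbits, " vs ", b$nbits)
  if (length(a$bits) == 0 && length(b$bits) == 0) return(1)
  length(intersect(a$bits, b$bits)) / length(union(a$bits, b$bits))
}

#' Greedy diversity selection (leader algorithm)
#'
#' Walks a score-ranked list and keeps a molecule iff its Tanimoto similarity
#' to every already-kept molecule is strictly below `simThreshold`. The
#' top-ranked molecule is always kept.
#'
#' @param mols list of [Molecule-class] objects, ranked best-first.
#' @param simThreshold similarity threshold in (0, 1] (default 0.6).
#' @param radius,nbits fingerprint parameters.
#' @return The kept molecules (a subset of `mols`, in rank order), with an
#'   attribute `kept` giving their indices in the input.
#' @export
diversityPick <- function(mols, simThreshold = 0.6, radius = 2L,
                          nbits = 2048L) {
  if (simThreshold <= 0 || simThreshold > 1)
    stop("simThreshold must lie in (0, 1]")
  if (length(mols) == 0) return(mols)
  fps <- lapply(mols, fingerprint, radius = radius, nbits = nbits)
  kept <- integer(0)
  for (i in seq_along(mols)) {
    sims <- vapply(kept, function(k) tanimoto(fps[[i]], fps[[k]]), numeric(1))
    if (all(sims < simThreshold)) kept <- c(kept, i)
  }
  out <- mols[kept]
  attr(out, "kept") <- kept
  out
}
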