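# Minimal s-orbital Gaussian-basis electronic-structure engine.
#
# Supports contracted s-type Gaussian bases on H and He centers; all one- and
# two-electron integrals have closed forms involving only the Boys function
# F0. States come from exact diagonalization (full CI) in the orthogonalized
# orbital basis, which makes monomer spectra, transition densities and
# densities exact within the chosen basis - precisely what the dispersion
# formulas need for machine-precision cross-checks.

boys_f0 <- function(t) {
  out <- numeric(length(t))
  small <- t < 1e-10
  out[small] <- 1 - t[small] / 3
  tb <- t[!small]
  out[!small] <- 0.5 * sqrt(pi / tb) * (2 * pnorm(sqrt(2 * tb)) - 1)
  out
}

# contraction data for normalized s primitives
s_basis_for <- function(element, basis = "sto-3g") {
  element <- toupper(element)
  if (basis == "sto-3g") {
    tab <- list(
      H = list(exps = c(3.42525091, 0.62391373, 0.16885540),
               coefs = c(0.15432897, 0.53532814, 0.44463454)),
      HE = list(exps = c(6.36242139, 1.15892300, 0.31364979),
                coefs = c(0.15432897, 0.53532814, 0.44463454))
    )
  } else if (basis == "sg1") {
    # single s Gaussian; H exponent is the variational optimum for the H atom
    tab <- list(H = list(exps = 0.28294212, coefs = 1.0),
                HE = list(exps = 0.7739, coefs = 1.0))
  } else {
    stop(sprintf("unknown basis '%s' (supported: sto-3g, sg1)", basis))
  }
  if (is.null(tab[[element]])) {
    stop(sprintf("element '%s' not supported by the s-orbital engine", element))
  }
  tab[[element]]
}

element_z <- function(element) {
  z <- c(H = 1L, HE = 2L)
  out <- z[toupper(element)]
  if (any(is.na(out))) stop("only H and He are supported")
  as.integer(out)
}

# one shell per atom: center, primitive exponents, normalized contraction
build_shells <- function(elements, coords, basis = "sto-3g") {
  shells <- lapply(seq_along(elements), function(i) {
    b <- s_basis_for(elements[i], basis)
    norm <- (2 * b$exps / pi)^0.75
    list(center = coords[i, ], exps = b$exps, coefs = b$coefs * norm)
  })
  # renormalize each contracted function
  for (i in seq_along(shells)) {
    s <- shells[[i]]
    ov <- prim_pair(s, s)
    self <- sum(ov$cc * (pi / ov$p)^1.5 * exp(-ov$mu * ov$R2))
    shells[[i]]$coefs <- s$coefs / sqrt(self)
  }
  shells
}

# all primitive pair quantities for two contracted s shells
prim_pair <- function(sa, sb) {
  g <- expand.grid(i = seq_along(sa$exps), j = seq_along(sb$exps))
  al <- sa$exps[g$i]; be <- sb$exps[g$j]
  p <- al + be
  R2 <- sum((sa$center - sb$center)^2)
  Px <- (al * sa$center[1] + be * sb$center[1]) / p
  Py <- (al * sa$center[2] + be * sb$center[2]) / p
  Pz <- (al * sa$center[3] + be * sb$center[3]) / p
  list(cc = sa$coefs[g$i] * sb$coefs[g$j], al = al, be = be, p = p,
       mu = al * be / p, R2 = R2, P = cbind(Px, Py, Pz))
}

ao_integrals <- function(shells, charges, positions) {
  n <- length(shells)
  S <- T_ <- V <- matrix(0, n, n)
  pairs <- vector("list", n * n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    pp <- prim_pair(shells[[a]], shells[[b]])
    pairs[[(a - 1L) * n + b]] <- pp
    ew <- pp$cc * exp(-pp$mu * pp$R2)
    S[a, b] <- sum(ew * (pi / pp$p)^1.5)
    T_[a, b] <- sum(ew * pp$mu * (3 - 2 * pp$mu * pp$R2) * (pi / pp$p)^1.5)
    v <- 0
    for (k in seq_along(charges)) {
      if (charges[k] == 0) next
      RPC2 <- rowSums(sweep(pp$P, 2L, positions[k, ], `-`)^2)
      v <- v - charges[k] * sum(ew * (2 * pi / pp$p) * boys_f0(pp$p * RPC2))
    }
    V[a, b] <- v
  }
  eri <- array(0, dim = c(n, n, n, n))
  for (a in seq_len(n)) for (b in seq_len(a)) {
    pab <- pairs[[(a - 1L) * n + b]]
    eab <- pab$cc * exp(-pab$mu * pab$R2)
    for (c in seq_len(n)) for (d in seq_len(c)) {
      if ((c - 1L) * n + d > (a - 1L) * n + b) next
      pcd <- pairs[[(c - 1L) * n + d]]
      ecd <- pcd$cc * exp(-pcd$mu * pcd$R2)
      # vectorized over all primitive quadruples
      pq <- outer(pab$p, pcd$p, `+`)
      fac <- 2 * pi^2.5 / (outer(pab$p, pcd$p) * sqrt(pq))
      PQ2 <- outer(pab$P[, 1], pcd$P[, 1], `-`)^2 +
        outer(pab$P[, 2], pcd$P[, 2], `-`)^2 +
        outer(pab$P[, 3], pcd$P[, 3], `-`)^2
      tt <- outer(pab$p, pcd$p) / pq * PQ2
      val <- sum(outer(eab, ecd) * fac * boys_f0(tt))
      for (idx in unique(list(c(a, b, c, d), c(b, a, c, d), c(a, b, d, c),
                              c(b, a, d, c), c(c, d, a, b), c(d, c, a, b),
                              c(c, d, b, a), c(d, c, b, a)))) {
        eri[idx[1], idx[2], idx[3], idx[4]] <- val
      }
    }
  }
  list(S = S, T = T_, V = V, eri = eri)
}

# orthonormal molecular orbitals from the core Hamiltonian
core_orbitals <- function(S, h) {
  es <- eigen(S, symmetric = TRUE)
  if (min(es$values) < 1e-8) stop("basis near-linear dependence")
  X <- es$vectors %*% diag(1 / sqrt(es$values), length(es$values)) %*% t(es$vectors)
  ho <- t(X) %*% h %*% X
  eh <- eigen(ho, symmetric = TRUE)
  X %*% eh$vectors[, order(eh$values), drop = FALSE]
}

# 4-index transform, small n
eri_mo_transform <- function(eri, C) {
  n <- ncol(C)
  g <- eri
  g <- apply(g, c(2, 3, 4), function(v) as.numeric(t(C) %*% v))
  g <- aperm(apply(g, c(1, 3, 4), function(v) as.numeric(t(C) %*% v)), c(2, 1, 3, 4))
  g <- aperm(apply(g, c(1, 2, 4), function(v) as.numeric(t(C) %*% v)), c(2, 3, 1, 4))
  aperm(apply(g, c(1, 2, 3), function(v) as.numeric(t(C) %*% v)), c(2, 3, 4, 1))
}

# ---- full CI machinery (small determinant spaces) -------------------------

fci_strings <- function(n_orb, n_el) {
  if (n_el == 0L) return(list(integer(0)))
  cm <- utils::combn(n_orb, n_el)
  lapply(seq_len(ncol(cm)), function(j) cm[, j])
}

string_key <- function(s) paste0("s", paste(s, collapse = ","))

string_index <- function(strings) {
  keys <- vapply(strings, string_key, character(1))
  setNames(seq_along(strings), keys)
}

# a_p^dagger a_q acting on each string: target index and phase (or 0)
epq_table <- function(strings, n_orb) {
  idx <- string_index(strings)
  tab <- array(0L, dim = c(length(strings), n_orb, n_orb, 2L))
  for (s in seq_along(strings)) {
    occ <- strings[[s]]
    for (q in occ) {
      pos <- match(q, occ)
      ph1 <- if (pos %% 2L == 1L) 1L else -1L
      rest <- occ[-pos]
      for (p in seq_len(n_orb)) {
        if (p %in% rest) next
        nb <- sum(rest < p)
        ph2 <- if (nb %% 2L == 0L) 1L else -1L
        new <- sort(c(rest, p))
        tab[s, p, q, 1L] <- idx[[string_key(new)]]
        tab[s, p, q, 2L] <- ph1 * ph2
      }
    }
  }
  tab
}

#' Full-CI solution in a small orbital space
#'
#' Exact diagonalization of the electronic Hamiltonian for `n_el = (n_alpha,
#' n_beta)` electrons in the orthonormal orbital basis defined by `h_mo` /
#' `eri_mo` (chemists' notation). Returns all eigenstates with their total-spin
#' expectation values, so singlet roots can be selected.
#'
#' @param h_mo one-electron Hamiltonian in the MO basis.
#' @param eri_mo two-electron integrals `(pq|rs)` in the MO basis.
#' @param n_alpha,n_beta electron counts per spin.
#' @param e_nuc nuclear repulsion added to every eigenvalue.
#' @return List: `energies` (ascending), `coefs` (columns are CI vectors),
#'   `s2` (S^2 expectation per state), `dets` (alpha/beta string index pairs),
#'   `strings_a`, `strings_b`.
#' @keywords internal
fci_solve <- function(h_mo, eri_mo, n_alpha, n_beta, e_nuc = 0) {
  n <- nrow(h_mo)
  sa <- fci_strings(n, n_alpha)
  sb <- fci_strings(n, n_beta)
  ta <- epq_table(sa, n)
  tb <- epq_table(sb, n)
  dets <- expand.grid(ia = seq_along(sa), ib = seq_along(sb))
  nd <- nrow(dets)
  det_idx <- matrix(seq_len(nd), length(sa), length(sb))

  # sigma = E_pq |det> for all dets, one (p,q), one spin at a time
  apply_epq <- function(vecidx, p, q) {
    # returns data.frame(from, to, phase) over dets for E_pq (both spins)
    resa <- ta[dets$ia, p, q, , drop = FALSE]
    dim(resa) <- c(nd, 2L)
    oka <- resa[, 1L] > 0L
    toa <- det_idx[cbind(resa[oka, 1L], dets$ib[oka])]
    resb <- tb[dets$ib, p, q, , drop = FALSE]
    dim(resb) <- c(nd, 2L)
    okb <- resb[, 1L] > 0L
    tob <- det_idx[cbind(dets$ia[okb], resb[okb, 1L])]
    list(from = c(which(oka), which(okb)), to = c(toa, tob),
         phase = c(resa[oka, 2L], resb[okb, 2L]))
  }

  # build dense E_pq matrices (nd x nd), reused for one- and two-electron parts
  Epq <- vector("list", n * n)
  for (p in seq_len(n)) for (q in seq_len(n)) {
    ap <- apply_epq(NULL, p, q)
    M <- matrix(0, nd, nd)
    M[cbind(ap$to, ap$from)] <- 0  # init
    for (k in seq_along(ap$from)) {
      M[ap$to[k], ap$from[k]] <- M[ap$to[k], ap$from[k]] + ap$phase[k]
    }
    Epq[[(p - 1L) * n + q]] <- M
  }

  H <- matrix(0, nd, nd)
  for (p in seq_len(n)) for (q in seq_len(n)) {
    if (h_mo[p, q] != 0) H <- H + h_mo[p, q] * Epq[[(p - 1L) * n + q]]
  }
  for (p in seq_len(n)) for (q in seq_len(n)) for (r in seq_len(n)) {
    for (s in seq_len(n)) {
      g <- eri_mo[p, q, r, s]
      if (abs(g) < 1e-14) next
      term <- Epq[[(p - 1L) * n + q]] %*% Epq[[(r - 1L) * n + s]]
      if (q == r) term <- term - Epq[[(p - 1L) * n + s]]
      H <- H + 0.5 * g * term
    }
  }

  ev <- eigen((H + t(H)) / 2, symmetric = TRUE)
  ord <- order(ev$values)
  energies <- ev$values[ord] + e_nuc
  coefs <- ev$vectors[, ord, drop = FALSE]

  # S^2 = S- S+ + Sz (Sz + 1); at Sz = 0 this is <S- S+>
  sa_after <- fci_strings(n, n_alpha + 1L)
  sb_after <- fci_strings(n, n_beta - 1L)
  idx_a2 <- string_index(sa_after)
  idx_b2 <- string_index(sb_after)
  sz <- (n_alpha - n_beta) / 2
  s2 <- vapply(seq_len(nd), function(st) {
    v <- coefs[, st]
    spv <- numeric(length(sa_after) * max(1L, length(sb_after)))
    for (d in seq_len(nd)) {
      if (v[d] == 0) next
      occ_b <- sb[[dets$ib[d]]]
      occ_a <- sa[[dets$ia[d]]]
      for (p in occ_b) {
        if (p %in% occ_a) next
        posb <- match(p, occ_b)
        phb <- if (posb %% 2L == 1L) 1 else -1
        newb <- occ_b[-posb]
        nba <- sum(occ_a < p)
        pha <- if (nba %% 2L == 0L) 1 else -1
        newa <- sort(c(occ_a, p))
        ia2 <- idx_a2[[string_key(newa)]]
        ib2 <- idx_b2[[string_key(newb)]]
        k <- (ib2 - 1L) * length(sa_after) + ia2
        spv[k] <- spv[k] + phb * pha * v[d]
      }
    }
    sum(spv^2) + sz * (sz + 1)
  }, numeric(1))

  list(energies = energies, coefs = coefs, s2 = s2, dets = dets,
       strings_a = sa, strings_b = sb, Epq = Epq, n_orb = n)
}

# spin-summed one-particle (transition) density matrix between CI states
fci_transition_1rdm <- function(fci, state_i, state_j) {
  n <- fci$n_orb
  ci <- fci$coefs[, state_i]
  cj <- fci$coefs[, state_j]
  g <- matrix(0, n, n)
  for (p in seq_len(n)) for (q in seq_len(n)) {
    g[p, q] <- as.numeric(ci %*% (fci$Epq[[(p - 1L) * n + q]] %*% cj))
  }
  g
}

# contracted s AO values (and Cartesian gradients) at grid points
ao_values <- function(shells, points, gradient = FALSE) {
  n <- length(shells)
  N <- nrow(points)
  vals <- matrix(0, N, n)
  gx <- gy <- gz <- if (gradient) matrix(0, N, n) else NULL
  for (a in seq_len(n)) {
    s <- shells[[a]]
    dx <- points[, 1] - s$center[1]
    dy <- points[, 2] - s$center[2]
    dz <- points[, 3] - s$center[3]
    r2 <- dx^2 + dy^2 + dz^2
    for (k in seq_along(s$exps)) {
      e <- s$coefs[k] * exp(-s$exps[k] * r2)
      vals[, a] <- vals[, a] + e
      if (gradient) {
        gx[, a] <- gx[, a] - 2 * s$exps[k] * dx * e
        gy[, a] <- gy[, a] - 2 * s$exps[k] * dy * e
        gz[, a] <- gz[, a] - 2 * s$exps[k] * dz * e
      }
    }
  }
  if (gradient) list(vals = vals, gx = gx, gy = gy, gz = gz) else list(vals = vals)
}
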