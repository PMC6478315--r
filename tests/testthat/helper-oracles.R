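# Independent brute-force oracles, written as naive loops with their own
# bookkeeping so they share no code path with the package internals.

KB_ORACLE <- 0.0019872041
KC_ORACLE <- 332.0636

# Bond-graph distances up to 3 via breadth-first search.
oracle_graph_dist <- function(n, pairs) {
  adj <- vector("list", n)
  if (!is.null(pairs) && nrow(pairs) > 0) {
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
  }
  gd <- matrix(Inf, n, n); diag(gd) <- 0
  for (src in seq_len(n)) {
    frontier <- src
    for (depth in 1:3) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[gd[src, nxt] > depth]
      if (length(nxt) == 0) break
      gd[src, nxt] <- depth
      frontier <- nxt
    }
  }
  gd
}

oracle_hydration <- function(sys, xyz, cutoff) {
  a <- sys$atoms
  gids <- sort(unique(a$group))
  v_full <- numeric(length(gids)); v_intra <- numeric(length(gids))
  for (gi in seq_along(gids)) {
    memb <- which(a$group == gids[gi])
    hv <- memb[a$element[memb] != "H"]
    repa <- if (length(hv)) hv[1] else memb[1]
    Rk <- a$rmin_half[repa]; sk <- a$solv_sigma[repa]
    for (m in seq_len(nrow(a))) {
      if (a$group[m] == gids[gi]) next
      d <- sqrt(sum((xyz[m, ] - xyz[repa, ])^2))
      if (d > cutoff) next
      d <- max(d, 1e-6)
      contrib <- a$solv_volume[m] * exp(-((d - Rk) / sk)^2) /
        (2 * pi^1.5 * sk * d^2)
      v_full[gi] <- v_full[gi] + contrib
      if (a$ligand[m] == a$ligand[repa]) v_intra[gi] <- v_intra[gi] + contrib
    }
  }
  list(full = pmin(v_full, 1), intra = pmin(v_intra, 1),
       gid_of = match(a$group, gids),
       rep_ligand = vapply(gids, function(g) {
         memb <- which(a$group == g)
         hv <- memb[a$element[memb] != "H"]
         a$ligand[if (length(hv)) hv[1] else memb[1]]
       }, logical(1)))
}

# Full mixed-resolution energy by naive loops.  Returns the same component
# names as total_energy().
oracle_energy <- function(sys, xyz = sys$xyz, cutoff = 10,
                          go_eps = 3.0, go_rhc = 1.7, go_cut = 8,
                          eps0 = 2, eps1 = 8, cc = 0.625) {
  a <- sys$atoms; n <- nrow(a)
  coarse_res <- sys$residues$region == "coarse"
  coarse_atom <- coarse_res[a$residue] & !a$ligand
  pairs <- rbind(as.matrix(sys$bonds[, c("i", "j")]),
                 if (!is.null(sys$ligand_bonds) && nrow(sys$ligand_bonds))
                   as.matrix(sys$ligand_bonds[, c("i", "j")]))
  gd <- oracle_graph_dist(n, pairs)
  hyd <- oracle_hydration(sys, xyz, cutoff)
  sums <- c(nb_lig = 0, int_aa_vdw = 0, int_aa_elec = 0, int_cg_vdw = 0,
            int_cg_elec = 0, nb_aa = 0, nb_cross = 0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (coarse_atom[i] && coarse_atom[j]) next
      if (gd[i, j] <= 2) next
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (d > cutoff) next
      d <- max(d, 1e-6)
      sv <- if (gd[i, j] == 3) 0.5 else 1
      se <- if (gd[i, j] == 3) 1 / 1.2 else 1
      rmin <- a$rmin_half[i] + a$rmin_half[j]
      epsp <- sqrt(a$epsilon[i] * a$epsilon[j])
      x <- (rmin / d)^6
      vdw <- min(epsp * (x^2 - 2 * x) * sv, 1e6)
      interaction <- xor(a$ligand[i], a$ligand[j])
      gi <- hyd$gid_of[i]; gj <- hyd$gid_of[j]
      vset <- if (interaction) hyd$full else hyd$intra
      s <- min(cc * (vset[gi] + vset[gj]), 1 - 1e-9)
      epsd <- d * (eps0 + (1 - s) * (eps1 - eps0))
      elec <- max(min(KC_ORACLE * a$charge[i] * a$charge[j] * se / (epsd * d),
                      1e6), -1e6)
      if (a$ligand[i] && a$ligand[j]) {
        sums["nb_lig"] <- sums["nb_lig"] + vdw + elec
      } else if (interaction) {
        if (coarse_atom[i] || coarse_atom[j]) {
          sums["int_cg_vdw"] <- sums["int_cg_vdw"] + vdw
          sums["int_cg_elec"] <- sums["int_cg_elec"] + elec
        } else {
          sums["int_aa_vdw"] <- sums["int_aa_vdw"] + vdw
          sums["int_aa_elec"] <- sums["int_aa_elec"] + elec
        }
      } else if (coarse_atom[i] || coarse_atom[j]) {
        sums["nb_cross"] <- sums["nb_cross"] + vdw + elec
      } else {
        sums["nb_aa"] <- sums["nb_aa"] + vdw + elec
      }
    }
  }

  bnd <- c(bb = 0, aa = 0, lig = 0, cgaa = 0)
  classify <- function(ix) {
    if (all(a$ligand[ix])) return("lig")
    if (all(coarse_res[a$residue[ix]] & a$backbone[ix])) return("bb")
    if (!any(coarse_res[a$residue[ix]])) return("aa")
    "cgaa"
  }
  for (r in seq_len(nrow(sys$bonds))) {
    b <- sys$bonds[r, ]
    d <- sqrt(sum((xyz[b$i, ] - xyz[b$j, ])^2))
    cl <- classify(c(b$i, b$j))
    bnd[cl] <- bnd[cl] + b$k * (d - b$r0)^2
  }
  for (r in seq_len(nrow(sys$angles))) {
    an <- sys$angles[r, ]
    v1 <- xyz[an$i, ] - xyz[an$j, ]; v2 <- xyz[an$k, ] - xyz[an$j, ]
    th <- acos(max(-1, min(1, sum(v1 * v2) /
                             sqrt(sum(v1^2) * sum(v2^2)))))
    cl <- classify(c(an$i, an$j, an$k))
    bnd[cl] <- bnd[cl] + an$kt * (th - an$theta0)^2
  }
  for (r in seq_len(nrow(sys$dihedrals))) {
    dh <- sys$dihedrals[r, ]
    b1 <- xyz[dh$j, ] - xyz[dh$i, ]; b2 <- xyz[dh$k, ] - xyz[dh$j, ]
    b3 <- xyz[dh$l, ] - xyz[dh$k, ]
    cr <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                           u[3] * v[1] - u[1] * v[3],
                           u[1] * v[2] - u[2] * v[1])
    n1 <- cr(b1, b2); n2 <- cr(b2, b3)
    m1 <- cr(n1, b2 / sqrt(sum(b2^2)))
    phi <- atan2(sum(m1 * n2), sum(n1 * n2))
    cl <- classify(c(dh$i, dh$j, dh$k, dh$l))
    bnd[cl] <- bnd[cl] + (dh$vn / 2) * (1 + cos(dh$n * phi - dh$gamma))
  }

  # Go term: native defined from the reference configuration sys$xyz.
  u_go <- 0
  coarse_list <- which(coarse_res)
  if (length(coarse_list) >= 2) {
    for (x in seq_along(coarse_list)) {
      for (y in seq_along(coarse_list)) {
        if (y <= x) next
        ri <- coarse_list[x]; rj <- coarse_list[y]
        if (abs(rj - ri) < 3) next
        cai <- sys$residues$calpha[ri]; caj <- sys$residues$calpha[rj]
        r0 <- sqrt(sum((sys$xyz[cai, ] - sys$xyz[caj, ])^2))
        d <- sqrt(sum((xyz[cai, ] - xyz[caj, ])^2))
        if (r0 < go_cut) {
          u_go <- u_go + go_eps * (5 * (r0 / d)^12 - 6 * (r0 / d)^10)
        } else if (d <= cutoff) {
          u_go <- u_go + 5 * go_eps * (go_rhc / d)^12
        }
      }
    }
  }

  u_bb <- bnd[["bb"]]
  u_cg <- u_bb + u_go
  u_ligand <- bnd[["lig"]] + sums[["nb_lig"]]
  u_vdw_int <- sums[["int_aa_vdw"]] + sums[["int_cg_vdw"]]
  u_elec_int <- sums[["int_aa_elec"]] + sums[["int_cg_elec"]]
  u_protein <- u_cg + bnd[["aa"]] + sums[["nb_aa"]] +
    bnd[["cgaa"]] + sums[["nb_cross"]]
  list(u_cg = u_cg, u_bb = u_bb, u_go = u_go,
       u_protein = u_protein, u_ligand = u_ligand,
       u_vdw_int = u_vdw_int, u_elec_int = u_elec_int,
       total = u_protein + u_ligand + u_vdw_int + u_elec_int)
}

# Naive agglomerative complete-linkage clustering with a diameter cutoff.
oracle_complete_linkage <- function(D, cutoff) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  repeat {
    best <- NULL; best_d <- Inf
    for (x in seq_along(clusters)) {
      for (y in seq_along(clusters)) {
        if (y <= x) next
        dd <- max(D[clusters[[x]], clusters[[y]]])
        if (dd < best_d - 1e-12) { best_d <- dd; best <- c(x, y) }
      }
    }
    if (is.null(best) || best_d > cutoff) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  asg <- integer(n)
  for (x in seq_along(clusters)) asg[clusters[[x]]] <- x
  asg
}

# Partitions equal up to relabelling: identical co-membership relations.
same_partition <- function(a, b) {
  identical(outer(a, a, `==`), outer(b, b, `==`))
}
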