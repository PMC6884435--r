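# The joint two-party protocol: phase 1 translates the facing-time table
# construction into comparison/min/max/product gates over shared period
# data; phase 2 runs the k-means variant entirely on shares, revealing only
# the final membership matrix and one convergence bit.  The gate sequence
# depends only on public shape parameters, never on secrets.

#' Secret-share a period table for the joint protocol
#'
#' Start time, end time and zone of every period are shared; the row count is
#' public.  Under the default `public` addressing, each nurse period carries
#' a public pseudonymous nurse index and each patient period a public patient
#' type (the output table is keyed by these anyway); under `oblivious`
#' addressing the indices are replaced by shared one-hot vectors, hiding
#' which rows belong to which nurse/type at a cost of extra multiplications.
#'
#' @param ctx an [mpc_session()].
#' @param periods period table (`tagID, st, et, zID, tagRole`).
#' @param nurse_ids ordered nurse identifiers (for nurse-scoped tables).
#' @param type_labels ordered patient type labels (for patient-scoped tables).
#' @param addressing `"public"` or `"oblivious"`.
#' @return object of class `shared_period_table`.
#' @export
share_period_table <- function(ctx, periods, nurse_ids = NULL, type_labels = NULL,
                               addressing = c("public", "oblivious")) {
  addressing <- match.arg(addressing)
  scope <- period_scope(periods$tagRole)
  if (scope == "mixed" && nrow(periods) > 0) {
    stop("share_period_table needs a single-role period table")
  }
  n <- nrow(periods)
  if (scope == "nurses_only" || (!is.null(nurse_ids) && is.null(type_labels))) {
    if (is.null(nurse_ids)) nurse_ids <- sort(unique(periods$tagID))
    idx <- match(periods$tagID, nurse_ids)
    if (anyNA(idx)) stop("input error: unknown nurse tag")
    labels <- nurse_ids
  } else {
    types <- if (n > 0) patient_type_of(periods$tagRole) else character(0)
    if (is.null(type_labels)) type_labels <- sort(unique(types))
    idx <- match(types, type_labels)
    if (anyNA(idx)) stop("input error: unknown patient type")
    labels <- type_labels
  }
  onehot <- NULL
  if (addressing == "oblivious" && n > 0) {
    oh <- matrix(0L, n, length(labels))
    oh[cbind(seq_len(n), idx)] <- 1L
    onehot <- mpc_share(ctx, as.vector(oh)) # column-major: (q-1)*n + i
    idx <- NULL
  }
  structure(
    list(
      n = n, scope = scope, addressing = addressing, labels = labels,
      st = mpc_share(ctx, periods$st), et = mpc_share(ctx, periods$et),
      zid = mpc_share(ctx, periods$zID), idx = idx, onehot = onehot
    ),
    class = "shared_period_table"
  )
}

empty_shared_table <- function(ctx, Nn, m, nurse_ids, type_labels, bins) {
  structure(
    list(cells = mpc_constant(ctx, 0, Nn * m), Nn = Nn, m = m,
         nurse_ids = nurse_ids, type_labels = type_labels, bins = bins),
    class = "shared_facing_table"
  )
}

#' Secure construction of the facing-time table
#'
#' For every (patient period, nurse period) pair the protocol computes a
#' shared zone-equality bit, the shared overlap `smin(et) - smax(st)`, a
#' positivity bit, and one shared indicator per duration bin (from
#' comparisons of the overlap against the public bin boundaries, summing to
#' the positivity bit); the product of zone bit and bin indicator is
#' accumulated into the addressed cell.  Revealing the result equals the
#' plaintext [build_facing_table()] on the underlying secrets.
#'
#' @param ctx an [mpc_session()].
#' @param nurses,patients `shared_period_table`s (nurse / patient scope).
#' @param bins public [time_bins()].
#' @param n_zones,max_time public bounds on zone identifiers and timestamps
#'   (seconds), which set the comparison bit-lengths.
#' @return object of class `shared_facing_table` (cells stored row-major:
#'   nurse, then type, then bin).
#' @export
secure_build_table <- function(ctx, nurses, patients, bins,
                               n_zones = 15, max_time = 3600) {
  zb <- bits_for(n_zones)
  tb <- bits_for(max_time)
  nb <- bins$n_bins
  Nn <- length(nurses$labels)
  Ntype <- length(patients$labels)
  m <- Ntype * nb
  nP <- nurses$n
  pP <- patients$n
  if (nP == 0 || pP == 0) {
    return(empty_shared_table(ctx, Nn, m, nurses$labels, patients$labels, bins))
  }
  np <- nP * pP
  ip <- rep(seq_len(pP), times = nP) # patient period of each pair
  jn <- rep(seq_len(nP), each = pP)  # nurse period of each pair
  z <- mpc_eq(ctx, sv_slice(patients$zid, ip), sv_slice(nurses$zid, jn), zb)
  mn <- mpc_smin(ctx, sv_slice(patients$et, ip), sv_slice(nurses$et, jn), tb)
  mx <- mpc_smax(ctx, sv_slice(patients$st, ip), sv_slice(nurses$st, jn), tb)
  ov <- mpc_sub(mn, mx)
  pos <- mpc_ge(ctx, ov, mpc_constant(ctx, 1, np), tb)
  if (nb >= 2) {
    # le_b = (ov <= TB_b), batched over all boundaries
    tbc <- mpc_constant(ctx, rep(bins$boundaries, each = np))
    le <- one_minus(mpc_lt(ctx, tbc, sv_rep(ov, times = nb - 1L), tb))
    le_first <- sv_slice(le, seq_len(np))
    le_last <- sv_slice(le, (nb - 2L) * np + seq_len(np))
    mm <- mpc_mul(ctx, sv_cat(le_first, pos), sv_cat(pos, le_last))
    bin_first <- sv_slice(mm, seq_len(np))
    bin_last <- mpc_sub(pos, sv_slice(mm, np + seq_len(np)))
    parts <- vector("list", nb)
    parts[[1]] <- bin_first
    if (nb >= 3) {
      for (b in 2:(nb - 1L)) {
        parts[[b]] <- mpc_sub(sv_slice(le, (b - 1L) * np + seq_len(np)),
                              sv_slice(le, (b - 2L) * np + seq_len(np)))
      }
    }
    parts[[nb]] <- bin_last
    binvec <- do.call(sv_cat, parts) # bin-major blocks of np
  } else {
    binvec <- pos
  }
  q <- mpc_mul(ctx, sv_slice(z, rep(seq_len(np), times = nb)), binvec)
  p <- ctx$field$p
  bin_of_elem <- rep(seq_len(nb), each = np)
  pair_of_elem <- rep(seq_len(np), times = nb)
  if (nurses$addressing == "public" && patients$addressing == "public") {
    cell <- (nurses$idx[jn[pair_of_elem]] - 1L) * m +
      (patients$idx[ip[pair_of_elem]] - 1L) * nb + bin_of_elem
    cells <- new_sv(fx_grouped_sum(q$s0, cell, Nn * m, p),
                    fx_grouped_sum(q$s1, cell, Nn * m, p), ctx$field)
  } else {
    if (is.null(patients$onehot) || is.null(nurses$onehot)) {
      stop("oblivious addressing requires both tables shared obliviously")
    }
    # multiply in the shared patient-type one-hot, then the nurse one-hot
    n1 <- np * nb
    t_rep <- rep(seq_len(Ntype), each = n1)
    q1_idx <- rep(seq_len(n1), times = Ntype)
    oh_t_idx <- (t_rep - 1L) * pP + ip[pair_of_elem[q1_idx]]
    q1 <- mpc_mul(ctx, sv_slice(q, q1_idx), sv_slice(patients$onehot, oh_t_idx))
    n2 <- n1 * Ntype
    n_rep <- rep(seq_len(Nn), each = n2)
    q2_idx <- rep(seq_len(n2), times = Nn)
    oh_n_idx <- (n_rep - 1L) * nP + jn[pair_of_elem[q1_idx[q2_idx]]]
    q2 <- mpc_mul(ctx, sv_slice(q1, q2_idx), sv_slice(nurses$onehot, oh_n_idx))
    cell <- (n_rep - 1L) * m + (t_rep[q2_idx] - 1L) * nb +
      bin_of_elem[q1_idx[q2_idx]]
    cells <- new_sv(fx_grouped_sum(q2$s0, cell, Nn * m, p),
                    fx_grouped_sum(q2$s1, cell, Nn * m, p), ctx$field)
  }
  structure(
    list(cells = cells, Nn = Nn, m = m, nurse_ids = nurses$labels,
         type_labels = patients$labels, bins = bins),
    class = "shared_facing_table"
  )
}

#' Reveal a shared facing table (testing / explicit-output use)
#'
#' @param ctx an [mpc_session()].
#' @param sft a `shared_facing_table`.
#' @return a `facing_table`.
#' @export
reveal_facing_table <- function(ctx, sft) {
  vals <- mpc_reveal(ctx, sft$cells, purpose = "output")
  counts <- matrix(as.integer(vals), nrow = sft$Nn, byrow = TRUE)
  rownames(counts) <- sft$nurse_ids
  nb <- sft$bins$n_bins
  colnames(counts) <- paste(rep(sft$type_labels, each = nb),
                            rep(sft$bins$labels, length(sft$type_labels)), sep = "_")
  structure(
    list(counts = counts, nurse_ids = sft$nurse_ids,
         type_labels = sft$type_labels, bins = sft$bins),
    class = "facing_table"
  )
}

# worst-case centroid bounds after t update rounds (exact big-integer)
kmeans_bounds <- function(Nn, m, y_bound, iterations) {
  Y <- as_bn(y_bound)
  w <- "1"
  x <- Y
  grow <- as_bn(Nn + 1)
  wlist <- character(iterations)
  xlist <- character(iterations)
  slist <- character(iterations)
  clist <- character(iterations)
  for (r in seq_len(iterations)) {
    # comparisons in round r use the state after r-1 updates
    s_bound <- bn_mul(as_bn(m), bn_add(bn_mul(x, x),
                                       bn_mul("2", bn_mul(w, bn_mul(x, Y)))))
    c_bound <- bn_mul(bn_mul(w, w), s_bound)
    slist[r] <- s_bound
    clist[r] <- c_bound
    x <- bn_add(bn_mul(w, bn_mul(as_bn(Nn), Y)), x)
    w <- bn_mul(w, grow)
    wlist[r] <- w
    xlist[r] <- x
  }
  list(w = wlist, x = xlist, score = slist, comparison = clist,
       score_bits = bits_for(clist[iterations]))
}

lt_cost <- function(n, bits) {
  list(triples = n * (2L * bits - 1L), rand_bits = n * bits, pow2_masks = n)
}

#' Plan the circuit budget of a secure run
#'
#' Computes, from public shape parameters only, the worst-case bit-length of
#' every wire class (zones, times, k-means comparison inputs, centroid
#' denominators) and the exact amount of preprocessed material (Beaver
#' triples, shared random bits, comparison masks, zero-test masks) both
#' phases will consume.  Callers compare the bounds against the field before
#' executing; [secure_kmeans()] refuses to run on a violated budget.
#'
#' @param shape named list with `Nn`, `Nptype`, `Ntimebins`, `nP`, `pP`, `k`,
#'   `iterations`, and optionally `n_zones` (default 15), `max_time` (default
#'   3600) and `addressing` (default `"public"`).
#' @param field a [field_spec()].
#' @return list with `bits` (per wire class), `bounds` (exact worst-case
#'   magnitudes as decimal strings), `counts` (per phase and total), and `ok`
#'   with human-readable `reasons` when the field cannot host the circuit.
#' @export
plan_budget <- function(shape, field = field_mersenne127()) {
  defaults <- list(n_zones = 15L, max_time = 3600L, addressing = "public")
  shape <- modifyList(defaults, shape)
  Nn <- shape$Nn; Ntype <- shape$Nptype; nb <- shape$Ntimebins
  nP <- shape$nP; pP <- shape$pP; k <- shape$k; R <- shape$iterations
  m <- Ntype * nb
  zb <- bits_for(shape$n_zones)
  tb <- bits_for(shape$max_time)
  y_bound <- as.numeric(nP) * as.numeric(pP)
  kb <- kmeans_bounds(Nn, m, y_bound, R)
  sb <- kb$score_bits
  np <- nP * pP
  # ---- phase 1 (counts mirror secure_build_table) ----
  lt1 <- Map(lt_cost,
             n = list(2 * np, np, np, np, np * max(nb - 1L, 0L)),
             bits = list(zb, tb, tb, tb, tb))
  p1 <- Reduce(function(a, b) Map(`+`, a, b), lt1)
  extra_mul <- np * (1L + 2L + 2L) + if (nb >= 2) np * (2L + nb) else np
  p1$triples <- p1$triples + extra_mul
  if (shape$addressing == "oblivious") {
    p1$triples <- p1$triples + np * nb * Ntype + np * nb * Ntype * Nn
  }
  p1$nonzero_masks <- 0L
  # ---- phase 2 (counts mirror secure_kmeans) ----
  p2 <- list(triples = 0, rand_bits = 0, pow2_masks = 0, nonzero_masks = 0)
  if (k >= 2) {
    per_mul <- 2 * k * m + k + Nn * k * (k - 1) + Nn * k * m +
      Nn * k * max(k - 2L, 0L) + Nn * max(k - 2L, 0L) + Nn * (k - 1L) +
      Nn * k * m + k * m + k
    per_lt <- lt_cost(Nn * k * (k - 1L), sb)
    p2$triples <- R * (per_mul + per_lt$triples)
    p2$rand_bits <- R * per_lt$rand_bits
    p2$pow2_masks <- R * per_lt$pow2_masks
  } else {
    p2$triples <- R * (Nn * m + m + 1L)
  }
  if (R >= 2) {
    p2$triples <- p2$triples + Nn * k + 1L
    p2$nonzero_masks <- 1L
  }
  total <- Map(`+`, p1, p2)
  # ---- feasibility ----
  reasons <- character(0)
  wire_bits <- c(zone = zb, time = tb, score = sb)
  for (nm in names(wire_bits)) {
    b <- wire_bits[[nm]]
    if (b + field$kappa + 2L > field$bitlen ||
        bn_cmp(two_pow_chr(b + field$kappa + 2L), field$p) > 0) {
      reasons <- c(reasons, sprintf(
        "%s comparisons need %d bits but the field leaves only %d",
        nm, b, field$bitlen - field$kappa - 2L))
    }
  }
  for (cls in c("x", "w", "comparison")) {
    worst <- kb[[cls]][R]
    if (bn_cmp(worst, field$signed_bound) > 0) {
      reasons <- c(reasons, sprintf("wire class '%s' exceeds the signed bound", cls))
    }
  }
  list(
    bits = list(zone = zb, time = tb, score = sb),
    bounds = list(y = as_bn(y_bound), w = kb$w[R], x = kb$x[R],
                  comparison = kb$comparison[R]),
    counts = list(phase1 = p1, phase2 = p2, total = total),
    ok = length(reasons) == 0,
    reasons = reasons
  )
}

#' Secure k-means clustering on a shared facing table
#'
#' Initial centroid indices are chosen publicly from the seed (the same draw
#' as the plaintext path); scores, comparison bits, membership entries,
#' cluster sizes and centroid numerators/denominators all remain shared
#' throughout.  Only the final tie-broken membership matrix and a one-bit
#' randomised zero-test of the last assignment change are revealed.  The
#' revealed result equals [facing_kmeans()] on the revealed table with the
#' same configuration.
#'
#' @param ctx an [mpc_session()].
#' @param sft a `shared_facing_table` (or any shared matrix wrapped as one).
#' @param config a [kmeans_config()] (`paper_variant` rules).
#' @param y_bound public upper bound on table entries (e.g. `nP * pP`); sets
#'   the comparison bit-length via the budget.
#' @return list with `membership` (revealed binary matrix), `converged`
#'   (0/1), `init_indices`.
#' @export
secure_kmeans <- function(ctx, sft, config, y_bound) {
  Nn <- as.integer(sft$Nn)
  m <- as.integer(sft$m)
  k <- as.integer(config$k)
  R <- as.integer(config$iterations)
  if (k > Nn) stop("configuration error: k must not exceed the number of nurses")
  kb <- kmeans_bounds(Nn, m, y_bound, R)
  sb <- kb$score_bits
  field <- ctx$field
  if (sb + field$kappa + 2L > field$bitlen ||
      bn_cmp(two_pow_chr(sb + field$kappa + 2L), field$p) > 0 ||
      bn_cmp(kb$comparison[R], field$signed_bound) > 0) {
    stop(sprintf(
      "configuration error: circuit budget violated (needs %d comparison bits; field leaves %d)",
      sb, field$bitlen - field$kappa - 2L))
  }
  idx <- draw_init_indices(Nn, k, config$seed)
  y <- sft$cells # row-major: (i-1)*m + l
  xall <- sv_slice(y, as.vector(vapply(idx, function(i) (i - 1L) * m + seq_len(m),
                                       integer(m)))) # (j-1)*m + l
  w <- mpc_constant(ctx, 1, k)
  y_idx_base <- rep((0:(Nn - 1L)) * m, times = m) + rep(seq_len(m), each = Nn)
  ms <- vector("list", R)
  if (k >= 2) {
    pj <- rep(seq_len(k), each = k)
    pj2 <- rep(seq_len(k), times = k)
    keep <- pj != pj2
    pj <- pj[keep]; pj2 <- pj2[keep]
    P <- length(pj)
    swap <- match(paste(pj2, pj), paste(pj, pj2))
    pos_list <- lapply(seq_len(k), function(j) which(pj == j)) # k-1 pairs each
  }
  for (r in seq_len(R)) {
    wrep <- sv_slice(w, rep(seq_len(k), each = m))
    if (k >= 2) {
      x2 <- mpc_mul(ctx, xall, xall)
      wx <- mpc_mul(ctx, wrep, xall)
      wxy <- mpc_mul(ctx, sv_slice(wx, rep(seq_len(k * m), each = Nn)),
                     sv_slice(y, rep(y_idx_base, times = k)))
      grpB <- rep((0:(k - 1L)) * Nn, each = m * Nn) + rep(seq_len(Nn), times = k * m)
      B <- new_sv(fx_grouped_sum(wxy$s0, grpB, Nn * k, field$p),
                  fx_grouped_sum(wxy$s1, grpB, Nn * k, field$p), field)
      A <- new_sv(fx_grouped_sum(x2$s0, rep(seq_len(k), each = m), k, field$p),
                  fx_grouped_sum(x2$s1, rep(seq_len(k), each = m), k, field$p), field)
      s <- mpc_sub(sv_slice(A, rep(seq_len(k), each = Nn)), mpc_mul_const(B, 2))
      w2 <- mpc_mul(ctx, w, w)
      u <- mpc_mul(ctx, sv_slice(w2, rep(pj2, each = Nn)),
                   sv_slice(s, (rep(pj, each = Nn) - 1L) * Nn + rep(seq_len(Nn), P)))
      ua <- sv_slice(u, (rep(swap, each = Nn) - 1L) * Nn + rep(seq_len(Nn), P))
      xi <- mpc_ge(ctx, ua, u, sb) # xi(i, j, j') in pair-major blocks of Nn
      slice_factor <- function(f) {
        sv_slice(xi, as.vector(vapply(seq_len(k), function(j) {
          (pos_list[[j]][f] - 1L) * Nn + seq_len(Nn)
        }, integer(Nn))))
      }
      Macc <- slice_factor(1L)
      if (k >= 3) for (f in 2:(k - 1L)) Macc <- mpc_mul(ctx, Macc, slice_factor(f))
      Mcols <- lapply(seq_len(k), function(j) sv_slice(Macc, (j - 1L) * Nn + seq_len(Nn)))
      pref <- NULL
      for (j in 2:k) {
        pref <- if (j == 2) one_minus(Mcols[[1]]) else {
          mpc_mul(ctx, pref, one_minus(Mcols[[j - 1L]]))
        }
        Mcols[[j]] <- mpc_mul(ctx, Mcols[[j]], pref)
      }
      M <- do.call(sv_cat, Mcols) # (j-1)*Nn + i
    } else {
      M <- mpc_constant(ctx, 1, Nn)
    }
    ms[[r]] <- M
    # centroid update: x' = w * sum_i M_ij y_i + x ; w' = w * (n_j + 1)
    M_idx <- rep((0:(k - 1L)) * Nn, each = m * Nn) + rep(seq_len(Nn), times = k * m)
    prod <- mpc_mul(ctx, sv_slice(M, M_idx), sv_slice(y, rep(y_idx_base, times = k)))
    grpS <- rep(seq_len(k * m), each = Nn)
    S <- new_sv(fx_grouped_sum(prod$s0, grpS, k * m, field$p),
                fx_grouped_sum(prod$s1, grpS, k * m, field$p), field)
    nj <- new_sv(fx_grouped_sum(M$s0, rep(seq_len(k), each = Nn), k, field$p),
                 fx_grouped_sum(M$s1, rep(seq_len(k), each = Nn), k, field$p), field)
    xall <- mpc_add(mpc_mul(ctx, wrep, S), xall)
    w <- mpc_mul(ctx, w, mpc_add_const(nj, 1))
  }
  converged <- 0L
  if (R >= 2) {
    diff <- mpc_sub(ms[[R]], ms[[R - 1L]])
    sq <- mpc_mul(ctx, diff, diff)
    tot <- new_sv(fx_grouped_sum(sq$s0, rep(1L, Nn * k), 1L, field$p),
                  fx_grouped_sum(sq$s1, rep(1L, Nn * k), 1L, field$p), field)
    converged <- as.integer(mpc_is_zero(ctx, tot))
  }
  Mrev <- matrix(as.integer(mpc_reveal(ctx, ms[[R]], "output")), nrow = Nn)
  rownames(Mrev) <- sft$nurse_ids
  list(membership = Mrev, converged = converged, init_indices = idx)
}
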