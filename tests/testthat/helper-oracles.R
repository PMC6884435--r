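# Independent oracles and small-instance builders used across the suite.
# Oracles deliberately use different algebra than the code paths they check.

# classify every (nurse period, patient period) pair by counting shared grid
# slots; independent of the min/max overlap arithmetic in the package
slot_oracle_facing <- function(nurse_periods, patient_periods, bins,
                               nurse_ids, type_labels, dt = 4) {
  nb <- bins$n_bins
  m <- length(type_labels) * nb
  counts <- matrix(0L, length(nurse_ids), m,
                   dimnames = list(nurse_ids, NULL))
  if (nrow(nurse_periods) == 0 || nrow(patient_periods) == 0) return(counts)
  ptypes <- sub("^patient:", "", patient_periods$tagRole)
  for (j in seq_len(nrow(nurse_periods))) {
    for (i in seq_len(nrow(patient_periods))) {
      if (nurse_periods$zID[j] != patient_periods$zID[i]) next
      slots_n <- seq(nurse_periods$st[j], nurse_periods$et[j] - dt, by = dt)
      slots_p <- seq(patient_periods$st[i], patient_periods$et[i] - dt, by = dt)
      ov <- dt * length(intersect(slots_n, slots_p))
      if (ov <= 0) next
      b <- if (length(bins$boundaries) == 0) 1L else {
        sum(bins$boundaries < ov) + 1L
      }
      ni <- match(nurse_periods$tagID[j], nurse_ids)
      ti <- match(ptypes[i], type_labels)
      col <- (ti - 1L) * nb + b
      counts[ni, col] <- counts[ni, col] + 1L
    }
  }
  counts
}

# exact rational comparison of squared distances via the direct
# (w*y - x)^2 / w^2 form (not the score identity used by the implementation)
rational_d2_leq <- function(y, ca, cb) {
  n <- nrow(y)
  m <- ncol(y)
  da <- bn_sub(bn_mul(rep(ca$w, m), as.character(y)), ca$x)
  db <- bn_sub(bn_mul(rep(cb$w, m), as.character(y)), cb$x)
  na_ <- bn_grouped_sum(bn_mul(da, da), rep(seq_len(n), m), n)
  nb_ <- bn_grouped_sum(bn_mul(db, db), rep(seq_len(n), m), n)
  bn_cmp(bn_mul(bn_mul(cb$w, cb$w), na_), bn_mul(bn_mul(ca$w, ca$w), nb_)) <= 0
}

# exhaustive nearest-centroid (lowest index wins ties) via the rational oracle
oracle_assign <- function(pts, centroids) {
  n <- nrow(pts)
  k <- length(centroids$w)
  M <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    best <- 1L
    for (j in 2:k) {
      cb <- new_centroids(centroids$x[j, , drop = FALSE], centroids$w[j])
      cbest <- new_centroids(centroids$x[best, , drop = FALSE], centroids$w[best])
      if (!rational_d2_leq(pts[i, , drop = FALSE], cbest, cb)) best <- j
    }
    M[i, best] <- 1L
  }
  M
}

# random disjoint grid periods for one tag
random_tag_periods <- function(tag, role, n_periods, zones, dt = 4, max_len = 10) {
  st <- integer(0); et <- integer(0); z <- integer(0)
  t <- dt * sample(0:2, 1)
  for (i in seq_len(n_periods)) {
    s <- t + dt * sample(0:2, 1)
    e <- s + dt * sample(1:max_len, 1)
    st <- c(st, s); et <- c(et, e); z <- c(z, sample(zones, 1))
    t <- e
  }
  data.frame(tagID = tag, st = st, et = et, zID = z, tagRole = role,
             stringsAsFactors = FALSE)
}

# a small random two-party instance: nurse periods, patient periods, layout
random_instance <- function(n_nurses, n_types, max_periods_side = 8, zones = 1:5) {
  nurse_ids <- sprintf("N%03d", seq_len(n_nurses))
  type_labels <- LETTERS[seq_len(n_types)]
  nsel <- sample(n_nurses, min(n_nurses, sample(2:4, 1)))
  np <- do.call(rbind, lapply(nurse_ids[nsel], function(id) {
    random_tag_periods(id, "nurse", sample(1:2, 1), zones)
  }))
  np <- head(np, max_periods_side)
  pats <- sprintf("P%03d", seq_len(sample(2:3, 1)))
  proles <- paste0("patient:", sample(type_labels, length(pats), replace = TRUE))
  pp <- do.call(rbind, Map(function(id, role) {
    random_tag_periods(id, role, sample(1:3, 1), zones)
  }, pats, proles))
  pp <- head(pp, max_periods_side)
  rownames(np) <- rownames(pp) <- NULL
  attr(np, "role_scope") <- "nurses_only"
  attr(pp, "role_scope") <- "patients_only"
  list(nurse_periods = np, patient_periods = pp,
       nurse_ids = nurse_ids, type_labels = type_labels,
       max_time = max(np$et, pp$et), n_zones = max(zones))
}

# find the seed whose public initial-centroid draw equals `want` (in order)
seed_for_init <- function(n, k, want) {
  for (s in 1:2000) {
    if (identical(draw_init_indices(n, k, s), as.integer(want))) return(s)
  }
  stop("no seed found for requested initial draw")
}
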