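# Independent brute-force oracles and small fixture builders. Everything
# here is deliberately naive (stack flood fill, triple loops, grid search)
# and shares no code with the package internals it checks.

# Flood-fill connected components of a logical 3-D mask.
oracle_components <- function(mask, connectivity = 26) {
  dims <- dim(mask)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  if (connectivity == 6) off <- off[rowSums(abs(off)) == 1, , drop = FALSE]
  lab <- array(0L, dims)
  comps <- list()
  for (s in which(mask)) {
    if (lab[s] > 0L) next
    cur <- length(comps) + 1L
    lab[s] <- cur
    stack <- s
    comp <- s
    while (length(stack) > 0) {
      v <- stack[[1]]
      stack <- stack[-1]
      co <- arrayInd(v, dims)
      for (m in seq_len(nrow(off))) {
        nb <- as.integer(co) + off[m, ]
        if (any(nb < 1) || any(nb > dims)) next
        li <- (nb[3] - 1) * dims[1] * dims[2] + (nb[2] - 1) * dims[1] + nb[1]
        if (mask[li] && lab[li] == 0L) {
          lab[li] <- cur
          stack <- c(stack, li)
          comp <- c(comp, li)
        }
      }
    }
    comps[[cur]] <- sort(comp)
  }
  comps
}

# canonical form for comparing component partitions
canon_components <- function(comps) {
  comps <- lapply(comps, function(x) as.numeric(sort(x)))
  comps[order(vapply(comps, min, numeric(1)))]
}

# Exhaustive SUVpeak: for every candidate centre, average over all voxels of
# the whole grid whose centre lies within the 1-ml sphere radius.
oracle_suvpeak <- function(vol, spacing, center_voxels, sphere_ml = 1.0) {
  r <- (3 * sphere_ml * 1000 / (4 * pi))^(1 / 3)
  dims <- dim(vol)
  best <- -Inf
  centers <- arrayInd(center_voxels, dims)
  for (ci in seq_len(nrow(centers))) {
    c0 <- centers[ci, ]
    vals <- c()
    for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) for (k in seq_len(dims[3])) {
      d2 <- ((i - c0[1]) * spacing[1])^2 + ((j - c0[2]) * spacing[2])^2 +
            ((k - c0[3]) * spacing[3])^2
      if (d2 <= r^2) vals <- c(vals, vol[i, j, k])
    }
    best <- max(best, mean(vals))
  }
  best
}

# Hand-written Cox partial log-likelihood (single covariate, no ties) and an
# iteratively refined grid search for its maximizer.
oracle_cox_beta <- function(time, event, x, lo = -20, hi = 20) {
  pl <- function(b) {
    lp <- b * x
    s <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      s <- s + lp[i] - log(sum(exp(lp[risk])))
    }
    s
  }
  for (pass in 1:5) {
    grid <- seq(lo, hi, length.out = 201)
    v <- vapply(grid, pl, numeric(1))
    b <- grid[which.max(v)]
    w <- (hi - lo) / 200
    lo <- b - 2 * w
    hi <- b + 2 * w
  }
  b
}

# Gonen-Heller concordance by a double loop over unordered pairs.
oracle_cpe <- function(eta) {
  n <- length(eta)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- eta[i] - eta[j]
    tot <- tot + if (d == 0) 0.5 else 1 / (1 + exp(-abs(d)))
  }
  tot / (n * (n - 1) / 2)
}

# A lesion table of n_per_patient foci per patient (half suspicious),
# volumes/SUVmax drawn from wide log-normals.
make_lesion_table <- function(n_patients, n_per_patient, seed = 1,
                              measurable = NULL) {
  set.seed(seed)
  regions <- c("bones", "lymph nodes", "lung", "liver")
  do.call(rbind, lapply(seq_len(n_patients), function(p) {
    n <- n_per_patient
    data.frame(
      patient_id = sprintf("P%03d", p),
      focus_id = sprintf("F%03d", seq_len(n)),
      body_part = "thorax",
      region = sample(regions, n, replace = TRUE),
      subregion = ifelse(stats::runif(n) < 0.5, "spine", NA_character_),
      volume_ml = stats::rlnorm(n, log(3), 1),
      suvmax = pmax(4, stats::rlnorm(n, log(7), 0.4)),
      suvpeak = NA_real_,
      measurable = measurable %||% (stats::runif(n) < 0.7),
      classification = rep(c("suspicious", "unsuspicious"), length.out = n),
      stringsAsFactors = FALSE)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# match table built directly from per-focus status vectors
make_matches <- function(patient_id, status, measurable = TRUE) {
  data.frame(patient_id = patient_id,
             ref_focus_id = sprintf("F%04d", seq_along(status)),
             cand_focus_id = sprintf("F%04d", seq_along(status)),
             ref_class = ifelse(status %in% c("TP", "FN"), "suspicious", "unsuspicious"),
             cand_class = ifelse(status %in% c("TP", "FP"), "suspicious", "unsuspicious"),
             status = status, measurable = measurable,
             has_subregion = FALSE,
             match_body_part = NA, match_region = NA,
             match_subregion = NA, match_most_detailed = NA,
             stringsAsFactors = FALSE)
}

# tiny uncensored survival fixture
surv_records <- function(time, event, ...) {
  data.frame(patient_id = sprintf("S%03d", seq_along(time)),
             time_months = time, event = event, ...,
             stringsAsFactors = FALSE)
}
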