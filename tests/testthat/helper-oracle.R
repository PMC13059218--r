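# Brute-force oracle: plain loops and sorts, independent of the package's
# vectorized implementation. Used to verify every stage exactly on small
# fixtures.

oracle_median <- function(x) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n == 0L) return(NA_real_)
  if (n %% 2L == 1L) x[(n + 1L) / 2L] else (x[n / 2L] + x[n / 2L + 1L]) / 2
}

# Full pipeline by loops: individual cut-offs, per-cell shares, share
# cut-offs, occupation flags, indices and quadrants.
oracle_pipeline <- function(survey, items, map, n_min = 1L) {
  ids <- items$item_id
  aligned <- list()
  cutoffs <- setNames(numeric(length(ids)), ids)
  for (i in seq_along(ids)) {
    v <- survey[[ids[i]]]
    a <- if (items$adverse_high[i]) v else
      items$scale_min[i] + items$scale_max[i] - v
    aligned[[ids[i]]] <- a
    cutoffs[ids[i]] <- oracle_median(a)
  }
  group_of <- map$jem_group_id[match(survey$occupation_code,
                                     map$occupation_code)]
  cells <- unique(data.frame(group = group_of, gender = survey$gender,
                             stringsAsFactors = FALSE))
  cells <- cells[!is.na(cells$group), , drop = FALSE]
  cells <- cells[order(cells$group, cells$gender), , drop = FALSE]

  shares <- list()
  for (r in seq_len(nrow(cells))) {
    sel <- which(!is.na(group_of) & group_of == cells$group[r] &
                   survey$gender == cells$gender[r])
    row <- list(group = cells$group[r], gender = cells$gender[r])
    for (id in ids) {
      vals <- aligned[[id]][sel]
      flags <- vals > cutoffs[id]
      nn <- sum(!is.na(flags))
      row[[paste0("share_", id)]] <-
        if (nn < n_min) NA_real_ else 100 * sum(flags, na.rm = TRUE) / nn
      row[[paste0("n_", id)]] <- nn
    }
    shares[[r]] <- row
  }
  cell_df <- do.call(rbind, lapply(shares, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))

  share_cuts <- setNames(numeric(length(ids)), ids)
  for (id in ids) {
    share_cuts[id] <- oracle_median(cell_df[[paste0("share_", id)]])
  }
  for (id in ids) {
    cell_df[[paste0("exp_", id)]] <-
      cell_df[[paste0("share_", id)]] > share_cuts[id]
  }

  d_ids <- ids[items$dimension == "demand"]
  c_ids <- ids[items$dimension == "control"]
  demand <- control <- rep(NA_integer_, nrow(cell_df))
  for (r in seq_len(nrow(cell_df))) {
    dflags <- unlist(cell_df[r, paste0("exp_", d_ids)])
    cflags <- unlist(cell_df[r, paste0("exp_", c_ids)])
    if (!anyNA(dflags)) demand[r] <- sum(dflags)
    if (!anyNA(cflags)) control[r] <- sum(cflags)
  }
  complete <- !is.na(demand) & !is.na(control)
  med_d <- oracle_median(demand[complete])
  med_c <- oracle_median(control[complete])
  quadrant <- rep(NA_character_, nrow(cell_df))
  for (r in seq_len(nrow(cell_df))) {
    if (is.na(demand[r]) || is.na(control[r])) next
    hd <- demand[r] > med_d
    lc <- control[r] > med_c
    quadrant[r] <- if (hd && lc) "high_strain" else if (hd) "active" else
      if (lc) "passive" else "low_strain"
  }
  cell_df$demand_index <- demand
  cell_df$control_index <- control
  cell_df$strain_quadrant <- quadrant

  list(cutoffs = cutoffs, cells = cell_df, share_cutoffs = share_cuts,
       index_medians = c(demand = med_d, control = med_c))
}
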