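# Independent day-by-day reference implementations of the supply-overlap
# rules, used to cross-check the interval-arithmetic engine. These work on
# explicit day grids and sets, never on the package's interval code.

# day-by-day episode oracle: walk calendar days, episode ends when more than
# `gap` drug-free days pass between the end of a supply run and the next
# dispense
oracle_episode <- function(day, supply, idx, gap = 120L, send = 10000L) {
  keep <- day >= idx
  day <- day[keep]; supply <- supply[keep]
  o <- order(day); day <- day[o]; supply <- supply[o]
  covered_max <- day[1L] + supply[1L] - 1L
  if (length(day) > 1L) for (j in 2L:length(day)) {
    # count the drug-free calendar days before this dispense one by one
    free_days <- 0L
    if (day[j] > covered_max + 1L)
      for (d in seq.int(covered_max + 1L, day[j] - 1L)) free_days <- free_days + 1L
    if (free_days > gap) break
    covered_max <- max(covered_max, day[j] + supply[j] - 1L)
  }
  min(covered_max, send)
}

# day-by-day level oracle. rx: data.frame(drug, day, supply) in integer days.
oracle_levels <- function(rx, idx, index_drugs, fup,
                          grace = 14L, omin = 30L, smin = 30L, win = 14L) {
  rx <- rx[rx$day + rx$supply - 1L >= idx & rx$day <= fup, , drop = FALSE]
  drugs <- unique(rx$drug)
  # covered-day sets per drug, clipped
  covset <- lapply(drugs, function(dr) {
    cd <- integer(0)
    for (j in which(rx$drug == dr))
      cd <- union(cd, seq.int(rx$day[j], rx$day[j] + rx$supply[j] - 1L))
    sort(cd[cd >= idx & cd <= fup])
  })
  names(covset) <- drugs
  # merged runs: break where the drug-free stretch exceeds the grace period;
  # a run's span includes its internal gap days
  runs <- list()
  for (dr in drugs) {
    cd <- covset[[dr]]
    if (!length(cd)) next
    brk <- c(0L, which(diff(cd) > grace + 1L), length(cd))
    for (b in seq_len(length(brk) - 1L)) {
      seg <- cd[(brk[b] + 1L):brk[b + 1L]]
      runs[[length(runs) + 1L]] <- list(drug = dr, s = min(seg), e = max(seg))
    }
  }
  if (!length(runs)) stop("no exposure")
  rs <- vapply(runs, `[[`, integer(1), "s")
  re <- vapply(runs, `[[`, integer(1), "e")
  rd <- vapply(runs, `[[`, character(1), "drug")
  o <- order(rs, rd)
  rs <- rs[o]; re <- re[o]; rd <- rd[o]
  span_days <- function(w) unique(unlist(lapply(w, function(j) seq.int(rs[j], re[j]))))
  drug_days <- function(dr) {
    w <- which(rd == dr)
    unique(unlist(lapply(w, function(j) seq.int(rs[j], re[j]))))
  }

  consumed <- rd %in% index_drugs & rs <= idx
  regimen <- sort(unique(index_drugs))
  lev_start <- idx; entry <- "initial"
  levels <- list(); events <- list()
  for (d in idx:fup) {
    repeat {
      cand <- which(!consumed & rs == d)
      cand <- cand[!(rd[cand] %in% regimen)]
      # continuation runs of current regimen drugs starting today
      cont <- which(!consumed & rs == d & rd %in% regimen)
      consumed[cont] <- TRUE
      if (!length(cand)) break
      i <- cand[order(rd[cand])][1L]
      if (re[i] - rs[i] + 1L < smin) {
        events[[length(events) + 1L]] <- list(kind = "attempt", drugs = rd[i],
                                              day = d)
        consumed[i] <- TRUE
        next
      }
      grp <- which(!consumed & rs >= d & rs <= d + win &
                     (re - rs + 1L) >= smin & !(rd %in% regimen))
      grp <- grp[!duplicated(rd[grp])]
      nd <- sort(rd[grp])
      if (d == lev_start) {  # absorbed, no event
        regimen <- sort(union(regimen, nd))
        consumed[grp] <- TRUE
        next
      }
      gdays <- span_days(grp)
      ovl <- vapply(regimen, function(r)
        length(intersect(drug_days(r), gdays)), integer(1))
      if (all(ovl >= omin)) {
        kind <- "add_on"; new_reg <- sort(union(regimen, nd))
      } else {
        kind <- "switch"
        new_reg <- sort(union(nd, regimen[ovl >= omin]))
      }
      events[[length(events) + 1L]] <- list(kind = kind, drugs = nd, day = d,
                                            multi = length(nd) >= 2L)
      levels[[length(levels) + 1L]] <- list(
        regimen = paste(regimen, collapse = "+"), entry = entry,
        duration = d - lev_start)
      regimen <- new_reg; lev_start <- d; entry <- kind
      consumed[grp] <- TRUE
    }
  }
  levels[[length(levels) + 1L]] <- list(
    regimen = paste(regimen, collapse = "+"), entry = entry,
    duration = fup - lev_start + 1L)
  list(levels = levels, events = events)
}

# random small timeline: single-drug start at day 0, up to 5 later
# prescriptions over up to 4 drugs
random_timeline <- function() {
  drugs <- c("sertraline", "escitalopram", "venlafaxine", "mirtazapine")
  n_extra <- sample(0:5, 1L)
  rx <- data.frame(drug = drugs[1L], day = 0L, supply = sample(5:90, 1L))
  if (n_extra > 0L)
    rx <- rbind(rx, data.frame(
      drug = sample(drugs, n_extra, replace = TRUE),
      day = sample(1:150, n_extra, replace = TRUE),
      supply = sample(5:60, n_extra, replace = TRUE)))
  rx
}

# run the engine on a plain timeline and return comparable structures
engine_levels <- function(rx, idx, index_drugs, fup, ...) {
  iv <- merge_exposures(data.frame(drug_id = rx$drug,
                                   dispense_date = as.Date(rx$day, origin = "2015-01-01"),
                                   days_supplied = rx$supply))
  res <- build_levels(iv, as.Date(idx, origin = "2015-01-01"), index_drugs,
                      as.Date(fup, origin = "2015-01-01"), ...)
  list(
    levels = lapply(seq_len(nrow(res$levels)), function(i) list(
      regimen = res$levels$regimen[i], entry = res$levels$entry_pattern[i],
      duration = res$levels$duration_days[i])),
    kinds = res$transitions$kind)
}

# simple permutation check of the trend test on a tiny table: Monte-Carlo
# distribution of the score statistic under fixed margins. Returns the
# mid-p (half weight on ties), the discrete analogue of the continuous
# normal-approximation p.
permutation_trend_p <- function(counts, totals, n_rep = 20000L) {
  scores <- seq_along(counts)
  grp <- rep(scores, totals)
  x <- unlist(mapply(function(k, n) c(rep(1L, k), rep(0L, n - k)),
                     counts, totals, SIMPLIFY = FALSE))
  obs <- abs(sum(grp * x) - sum(grp) * mean(x))
  above <- 0; ties <- 0
  for (r in seq_len(n_rep)) {
    xs <- sample(x)
    t_r <- abs(sum(grp * xs) - sum(grp) * mean(xs))
    if (t_r > obs + 1e-9) above <- above + 1
    else if (abs(t_r - obs) <= 1e-9) ties <- ties + 1
  }
  (above + ties / 2) / n_rep
}
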