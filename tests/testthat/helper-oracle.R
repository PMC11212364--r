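# Independent naive recomputation of every registry variable. Each
# quantity is derived by rescanning the raw period table with plain
# loops; no segmentation or statistics code is shared with the package.
# Used to cross-check compute_variables() on generated recordings.

oracle_variables <- function(rec, sE2_thr = 10, brief_thr = 3,
                             truncated = TRUE,
                             policy = "longest-include") {
  p <- rec$periods
  lab <- p$label; dur <- p$duration; st <- p$start
  n <- length(lab)
  total <- rec$total_duration
  t0 <- st[1]; endt <- t0 + total
  out <- list()
  put <- function(a, x) out[[a]] <<- as.numeric(x)[1]

  # truncation-aware mean/median for the member indices of a class;
  # the median limit uses a sentinel value larger than any duration
  tmean_tmed <- function(idx) {
    d <- dur[idx]
    if (!length(d)) return(c(NA_real_, NA_real_))
    if (truncated && n %in% idx) {
      u <- dur[setdiff(idx, n)]
      tobs <- dur[n]
      lo <- median(c(u, tobs))
      hi <- if (length(u) >= 2) median(c(u, sum(dur) + tobs + 1e9)) else Inf
      m <- if (identical(lo, hi)) lo
           else if (is.finite(hi)) (lo + hi) / 2
           else if (length(u) == 1) u
           else tobs
      a <- if (policy == "longest-include") {
        if (!length(u) || tobs > max(u)) mean(c(u, tobs)) else mean(u)
      } else if (policy == "include") mean(c(u, tobs))
        else if (length(u)) mean(u) else NA_real_
      c(a, m)
    } else c(mean(d), median(d))
  }
  nams <- function(suffix, idx, mx = FALSE) {
    put(paste0("n_", suffix), length(idx))
    put(paste0("s_", suffix), if (length(idx)) sum(dur[idx]) else 0)
    am <- tmean_tmed(idx)
    put(paste0("a_", suffix), am[1]); put(paste0("m_", suffix), am[2])
    if (mx) put(paste0("mx_", suffix),
                if (length(idx)) max(dur[idx]) else NA)
  }

  # --- probes by loop ---------------------------------------------------
  probe_id <- rep(NA_integer_, n); pid <- 0L
  for (i in seq_len(n)) if (lab[i] != "Np") {
    if (i == 1L || lab[i - 1L] == "Np") pid <- pid + 1L
    probe_id[i] <- pid
  }
  npr <- pid
  pr_dur <- numeric(npr); pr_start <- numeric(npr)
  for (k in seq_len(npr)) {
    rows <- which(!is.na(probe_id) & probe_id == k)
    pr_dur[k] <- sum(dur[rows]); pr_start[k] <- st[rows[1]]
  }
  pr_brief <- pr_dur < brief_thr

  # --- phloem phases by loop --------------------------------------------
  ph_first <- integer(0); ph_last <- integer(0)
  i <- 1L
  while (i <= n) {
    if (lab[i] %in% c("E1", "E2")) {
      j <- i
      while (j < n && lab[j + 1L] %in% c("E1", "E2")) j <- j + 1L
      ph_first <- c(ph_first, i); ph_last <- c(ph_last, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  nph <- length(ph_first)
  ph_dur <- ph_e2 <- numeric(nph); ph_reach <- logical(nph)
  for (k in seq_len(nph)) {
    rows <- ph_first[k]:ph_last[k]
    ph_dur[k] <- sum(dur[rows])
    ph_e2[k] <- sum(dur[rows][lab[rows] == "E2"])
    ph_reach[k] <- any(lab[rows] == "E2")
  }

  # --- derived period classes by loop -----------------------------------
  sgE1 <- frE1 <- firstE1 <- rep(FALSE, n)
  for (k in seq_len(nph)) {
    rows <- ph_first[k]:ph_last[k]
    if (!ph_reach[k]) {
      sgE1[rows[lab[rows] == "E1"]] <- TRUE
    } else {
      if (lab[rows[1]] == "E1") firstE1[rows[1]] <- TRUE
      for (r in rows) {
        if (lab[r] == "E1" && r > rows[1] && r < rows[length(rows)] &&
            lab[r - 1L] == "E2" && lab[r + 1L] == "E2") frE1[r] <- TRUE
      }
    }
  }
  sE2 <- lab == "E2" & dur > sE2_thr
  sgD <- rep(FALSE, n)
  for (i in which(lab == "D"))
    if (i == n || lab[i + 1L] != "E1") sgD[i] <- TRUE

  # --- pd groups by loop ------------------------------------------------
  pd_onset <- integer(0)
  for (i in seq_len(n))
    if (lab[i] == "pd" && (i == 1L || !(lab[i - 1L] %in%
                                        c("pd", "pdII-2", "pdII-3"))))
      pd_onset <- c(pd_onset, i)
  npd <- length(pd_onset)
  pd_total <- numeric(npd); pd_ii3 <- rep(NA_real_, npd)
  for (k in seq_len(npd)) {
    i <- pd_onset[k]; tot <- dur[i]
    if (i + 1L <= n && lab[i + 1L] == "pdII-2") {
      tot <- tot + dur[i + 1L]
      if (i + 2L <= n && lab[i + 2L] == "pdII-3") {
        tot <- tot + dur[i + 2L]; pd_ii3[k] <- dur[i + 2L]
      }
    }
    pd_total[k] <- tot
  }

  # --- non-sequential blocks --------------------------------------------
  nams("Np", which(lab == "Np"), mx = TRUE)
  nams("C", which(lab == "C"))
  nams("F", which(lab == "F"))
  nams("G", which(lab == "G"))
  nams("E1e", which(lab == "E1e"))
  nams("D", which(lab == "D"))
  nams("E1", which(lab == "E1"), mx = TRUE)
  nams("E2", which(lab == "E2"))
  put("mx_E2", if (any(lab == "E2")) max(dur[lab == "E2"]) else NA)
  nams("p-pd", which(lab == "p-pd"))
  put("n_sgD", sum(sgD))
  nams("sgE1", which(sgE1), mx = TRUE)
  nams("frE1", which(frE1), mx = TRUE)
  nams("sE2", which(sE2))
  np_rows <- which(lab == "Np")
  put("d_2Np", if (length(np_rows) >= 2) dur[np_rows[2]] else NA)

  # probes (plain statistics; the criterion applies to waveforms only)
  put("n_Pr", npr)
  put("s_Pr", if (npr) sum(pr_dur) else 0)
  put("a_Pr", if (npr) mean(pr_dur) else NA)
  put("m_Pr", if (npr) median(pr_dur) else NA)
  put("d_1Pr", if (npr) pr_dur[1] else NA)
  put("n_bPr", sum(pr_brief))

  # E12 phases (plain statistics on phase durations)
  e12_dur <- ph_dur[ph_reach]
  put("n_E12", length(e12_dur))
  put("s_E12", if (length(e12_dur)) sum(e12_dur) else 0)
  put("a_E12", if (length(e12_dur)) mean(e12_dur) else NA)
  put("m_E12", if (length(e12_dur)) median(e12_dur) else NA)
  put("mx_E12", if (length(e12_dur)) max(e12_dur) else NA)
  put("d_1st_E", if (nph) ph_dur[1] else NA)
  e2_rows <- which(lab == "E2")
  put("d_1st_E2", if (length(e2_rows)) dur[e2_rows[1]] else NA)
  put("a_1st E1_followed_E2",
      if (any(firstE1)) mean(dur[firstE1]) else NA)
  put("a_s_E2/phloem_ph", if (any(ph_reach)) mean(ph_e2[ph_reach]) else NA)

  # --- sequential times -------------------------------------------------
  put("t > 1Pr", if (npr) pr_start[1] - t0 else total)
  e_rows <- which(lab %in% c("E1", "E2"))
  se2_rows <- which(sE2)
  e12_start <- if (any(ph_reach)) st[ph_first[ph_reach][1]] else NA
  ptime <- function(event_start) {
    if (!npr) NA
    else if (is.na(event_start)) endt - pr_start[1]
    else event_start - pr_start[1]
  }
  put("t > 1E", ptime(if (length(e_rows)) st[e_rows[1]] else NA))
  put("t > 1E12", ptime(e12_start))
  put("t > 1E2", ptime(if (length(e2_rows)) st[e2_rows[1]] else NA))
  put("t > 1sE2", ptime(if (length(se2_rows)) st[se2_rows[1]] else NA))
  wtime <- function(rows) {
    if (!length(rows)) return(NA)
    st[rows[1]] - pr_start[probe_id[rows[1]]]
  }
  put("tPr > 1E/1Pr", wtime(e_rows))
  put("tPr > 1E2/1Pr", wtime(e2_rows))
  put("tPr > 1sE2/1Pr", wtime(se2_rows))
  ctime <- function(row) {
    s <- 0
    for (i in seq_len(row - 1L))
      if (!is.na(probe_id[i]) && probe_id[i] == probe_id[row] &&
          lab[i] == "C") s <- s + dur[i]
    s
  }
  put("tC > 1E/1Pr", if (length(e_rows)) ctime(e_rows[1]) else NA)
  put("tC > 1sE2/1Pr", if (length(se2_rows)) ctime(se2_rows[1]) else NA)
  prE <- unique(probe_id[e_rows])
  ct <- vapply(prE, function(k) ctime(min(e_rows[probe_id[e_rows] == k])),
               numeric(1))
  put("atC > 1E/Pr", if (length(ct)) mean(ct) else NA)
  put("mntC > 1E/Pr", if (length(ct)) min(ct) else NA)
  put("s_np.1E",
      if (length(e_rows)) {
        s <- 0
        for (i in seq_len(e_rows[1] - 1L)) if (lab[i] == "Np") s <- s + dur[i]
        s
      } else NA)

  # --- sequential counts ------------------------------------------------
  before <- function(rows) {
    if (!length(rows)) npr else probe_id[rows[1]] - 1L
  }
  before_brief <- function(rows) {
    if (!length(rows)) sum(pr_brief)
    else sum(pr_brief[seq_len(probe_id[rows[1]] - 1L)])
  }
  put("n_Pr > 1E", before(e_rows))
  put("n_brPr > 1E", before_brief(e_rows))
  put("n_Pr > 1E2", before(e2_rows))
  put("n_Pr > 1sE2", before(se2_rows))
  put("n_E2 > 1sE2",
      if (length(se2_rows)) sum(e2_rows < se2_rows[1]) else length(e2_rows))
  after <- function(rows, brief = FALSE) {
    if (!length(rows)) return(NA)
    ix <- setdiff(seq_len(npr), seq_len(probe_id[rows[1]]))
    if (brief) sum(pr_brief[ix]) else length(ix)
  }
  put("n_Pr.after1E", after(e_rows))
  put("n_bPr.after1E", after(e_rows, brief = TRUE))
  put("n_Pr < 1sE2", after(se2_rows))
  d1 <- d2 <- 0; any1 <- any2 <- FALSE
  for (i in seq_len(n - 1L)) if (lab[i] == "E1" && lab[i + 1L] == "E2") {
    d1 <- d1 + dur[i]; any1 <- TRUE
    if (sE2[i + 1L]) { d2 <- d2 + dur[i]; any2 <- TRUE }
  }
  put("d_E1followedbyE2", if (any1) d1 else NA)
  put("d_E1followedbysE2", if (any2) d2 else NA)

  # --- potential indices ------------------------------------------------
  s_pr <- if (npr) sum(pr_dur) else 0
  sC <- sum(dur[lab == "C"]); sE1d <- sum(dur[lab == "E1"])
  sE2d <- sum(dur[lab == "E2"])
  for (w in c("C", "F", "G", "E1", "E2"))
    put(paste0("%probtimein", w),
        if (s_pr > 0) 100 * sum(dur[lab == w]) / s_pr else NA)
  put("E2/C_ratio", if (sC > 0) sE2d / sC else NA)
  put("E2_index",
      if (length(e2_rows)) 100 * sE2d / (endt - st[e2_rows[1]]) else NA)
  e1_rows <- which(lab == "E1")
  put("E1_index",
      if (length(e1_rows)) 100 * sE1d / (endt - st[e1_rows[1]]) else NA)
  put("frE1_ratio",
      if (length(e1_rows)) sum(frE1) / length(e1_rows) else NA)
  put("%_sE2",
      if (length(e2_rows)) 100 * length(se2_rows) / length(e2_rows) else NA)
  put("%Phloem_ph_fail", if (nph) 100 * sum(!ph_reach) / nph else NA)

  # --- pd variables -----------------------------------------------------
  put("n_pd", npd)
  put("s_pd", if (npd) sum(pd_total) else 0)
  put("a_pd", if (npd) mean(pd_total) else NA)
  put("m_pd", if (npd) median(pd_total) else NA)
  for (pair in list(c("pd II-1", "pd"), c("pd II-2", "pdII-2"),
                    c("pd II-3", "pdII-3"))) {
    idx <- which(lab == pair[2])
    put(paste0("s_", pair[1]), if (length(idx)) sum(dur[idx]) else 0)
    am <- tmean_tmed(idx)
    put(paste0("a_", pair[1]), am[1]); put(paste0("m_", pair[1]), am[2])
  }
  put("n_pd/minC", if (sC > 0) npd / sC else NA)
  put("t > 1pd", if (npd) st[pd_onset[1]] - t0 else total)
  pd1 <- pd_onset[!is.na(probe_id[pd_onset]) & probe_id[pd_onset] == 1L]
  put("t > 1pd/1Pr",
      if (npr && length(pd1)) st[pd1[1]] - pr_start[1] else NA)
  prpd <- unique(probe_id[pd_onset])
  tpd <- vapply(prpd, function(k)
    min(st[pd_onset[probe_id[pd_onset] == k]]) - pr_start[k], numeric(1))
  put("at > 1pd/Pr", if (length(tpd)) mean(tpd) else NA)
  put("m_Pr > 1pd", if (length(tpd)) median(tpd) else NA)
  put("mnt_1pd/1pd", if (length(tpd)) min(tpd) else NA)
  put("n_pd/1Pr", if (npr) length(pd1) else NA)
  put("%_Pr_pd", if (npr) 100 * length(prpd) / npr else NA)
  put("n_Pr > 1pd", before(pd_onset))
  put("s_pdII-3/5pd", sum(pd_ii3[seq_len(min(npd, 5L))], na.rm = TRUE))

  unlist(out)
}
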