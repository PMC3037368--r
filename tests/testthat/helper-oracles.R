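# Independent brute-force oracles and toy-structure builders used across the
# suite. These deliberately share no code with the package implementations.

random_record <- function(n, seed, alphabet = c("A", "G", "K", "R", "D", "E",
                                                "S", "T", "L", "V", "P", "Q")) {
  withr::with_seed(seed,
    protein_record(paste0("rnd", seed),
                   paste(sample(alphabet, n, replace = TRUE), collapse = "")))
}

# Exhaustive zipper scan: every 7-strided window on every track, endpoints
# matching, <= k mismatches, >= min_core matches, kept only if no valid
# window strictly contains it. Fields recomputed from scratch.
brute_force_zipper <- function(record, min_core = 4, max_core_mismatch = 1,
                               permissive_core = c("A", "G"), comp_weight = 2) {
  s <- strsplit(record$sequence, "")[[1]]
  L <- length(s)
  cand <- list()
  for (start in 1:7) {
    track <- seq(start, L, by = 7)
    nm <- length(track)
    for (i in seq_len(nm)) for (j in i:nm) {
      w <- track[i:j]
      ok <- s[w] %in% permissive_core
      if (!ok[1] || !ok[length(ok)]) next
      if (sum(!ok) > max_core_mismatch) next
      if (sum(ok) < min_core) next
      cand[[length(cand) + 1L]] <- list(track_start = start, i = i, j = j, w = w)
    }
  }
  # maximality within the same track
  keep <- rep(TRUE, length(cand))
  for (x in seq_along(cand)) for (y in seq_along(cand)) {
    if (x == y) next
    a <- cand[[x]]; b <- cand[[y]]
    if (a$track_start == b$track_start && b$i <= a$i && a$j <= b$j &&
        !(b$i == a$i && b$j == a$j)) keep[x] <- FALSE
  }
  cand <- cand[keep]
  hits <- lapply(cand, function(cc) {
    w <- cc$w
    core <- w[s[w] %in% permissive_core]
    span_end <- min(core[length(core)] + 6, L)
    ncomp <- 0
    for (p in w) {
      if (p + 4 <= span_end && s[p + 3] %in% c("D", "E") &&
          s[p + 4] %in% c("K", "R")) ncomp <- ncomp + 1
    }
    list(span = c(core[1], span_end), core_positions = core,
         spacings = diff(core),
         phase = (3 - (core[1] - 1)) %% 7,
         n_complementary_pairs = ncomp,
         score = length(core) + comp_weight * ncomp)
  })
  if (length(hits) == 0) return(list())
  ord <- order(-vapply(hits, `[[`, 0, "score"),
               vapply(hits, function(h) h$span[1], 0),
               vapply(hits, `[[`, 0, "phase"))
  hits[ord]
}

# Naive sliding-window NLS scan with per-character comparison.
naive_scan_nls <- function(record) {
  s <- strsplit(record$sequence, "")[[1]]
  pats <- list(KxKK = c("K", ".", "K", "K"),
               KRxxK = c("K", "R", ".", ".", "K"),
               KPKRxKR = c("K", "P", "K", "R", ".", "K", "R"))
  std20 <- c("A","C","D","E","F","G","H","I","K","L",
             "M","N","P","Q","R","S","T","V","W","Y")
  out <- list()
  for (pid in names(pats)) {
    p <- pats[[pid]]
    if (length(s) < length(p)) next
    for (st in 1:(length(s) - length(p) + 1)) {
      win <- s[st:(st + length(p) - 1)]
      ok <- all(ifelse(p == ".", win %in% std20, win == p))
      if (ok) out[[length(out) + 1L]] <-
          list(pattern_id = pid, span = c(st, st + length(p) - 1),
               matched_text = paste(win, collapse = ""))
    }
  }
  out[order(vapply(out, function(h) h$span[1], 0),
            vapply(out, function(h) h$span[2], 0))]
}

# All-pairs O(n^2) contact oracle over plain loops.
brute_force_salt_bridges <- function(structure, cutoff = 4.0) {
  a <- structure$atoms
  ch <- unique(a$chain)[1:2]
  acid <- c("ASP", "GLU"); base <- c("LYS", "ARG", "HIS")
  grp <- function(i) {
    r <- a$resid[i]; e <- a$elety[i]
    (r %in% c(acid, base)) &&
      (e == "TIP" || e %in% c("OD1","OD2","OE1","OE2","NZ","NH1","NH2","NE","ND1","NE2"))
  }
  best <- list()
  for (i in which(a$chain == ch[1])) for (j in which(a$chain == ch[2])) {
    if (!grp(i) || !grp(j)) next
    ri <- a$resid[i]; rj <- a$resid[j]
    opp <- (ri %in% acid && rj %in% base) || (ri %in% base && rj %in% acid)
    if (!opp) next
    d <- sqrt(sum((as.numeric(a[i, c("x","y","z")]) -
                   as.numeric(a[j, c("x","y","z")]))^2))
    if (d > cutoff) next
    key <- paste(a$resno[i], a$resno[j])
    if (is.null(best[[key]]) || d < best[[key]]$d)
      best[[key]] <- list(resnoA = a$resno[i], resnoB = a$resno[j], d = d)
  }
  best
}

brute_force_hbonds <- function(structure, cutoff = 3.5) {
  a <- structure$atoms
  ch <- unique(a$chain)[1:2]
  polar_tips <- c("ASP","GLU","LYS","ARG","HIS","ASN","GLN","SER","THR","TYR","TRP")
  is_da <- function(i) {
    e <- a$elety[i]
    if (e %in% c("N", "O")) return(TRUE)
    if (e == "TIP" && a$resid[i] %in% polar_tips) return(TRUE)
    if (!(e %in% c("N","CA","C","O","CB","TIP")) && a$element[i] %in% c("N","O"))
      return(TRUE)
    FALSE
  }
  best <- list()
  for (i in which(a$chain == ch[1])) for (j in which(a$chain == ch[2])) {
    if (!is_da(i) || !is_da(j)) next
    if (a$element[i] != "O" && a$element[j] != "O") next
    d <- sqrt(sum((as.numeric(a[i, c("x","y","z")]) -
                   as.numeric(a[j, c("x","y","z")]))^2))
    if (d > cutoff) next
    key <- paste(a$resno[i], a$resno[j])
    if (is.null(best[[key]]) || d < best[[key]]$d)
      best[[key]] <- list(resnoA = a$resno[i], resnoB = a$resno[j], d = d)
  }
  best
}

# Minimal structure3d builder for constructed toys.
toy_structure <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(chain = r$chain %||% "A", resno = r$resno, resid = r$resid,
               elety = r$elety,
               element = r$element %||%
                 ifelse(r$elety %in% c("N", "O"), r$elety, "C"),
               x = r$xyz[1], y = r$xyz[2], z = r$xyz[3],
               charge = r$charge %||% 0, radius = r$radius %||% 1.7,
               stringsAsFactors = FALSE)
  }))
  structure3d(df)
}

atom <- function(chain, resno, resid, elety, xyz, charge = NULL,
                 radius = NULL, element = NULL) {
  list(chain = chain, resno = resno, resid = resid, elety = elety,
       xyz = xyz, charge = charge, radius = radius, element = element)
}

rotation_matrix <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
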