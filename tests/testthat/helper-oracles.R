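# Independent brute-force oracles. These deliberately re-derive each
# quantity from first principles (per-base expansion, path
# enumeration, exhaustive scanning) so they share no code with the
# implementations they check.

# per-base truncated mean: expand runs, sort, trim floor-count tails
bruteTad <- function(intervals, genome_length, central_fraction) {
  depths <- rep(0, genome_length)
  for (j in seq_len(nrow(intervals))) {
    depths[(intervals$start[j] + 1):intervals$end[j]] <- intervals$depth[j]
  }
  k <- floor(genome_length * (1 - central_fraction) / 2 + 1e-9)
  s <- sort(depths)
  mean(s[(k + 1):(genome_length - k)])
}

# root path by raw parent-vector walking (no package tree methods)
brutePath <- function(taxid, parent_of) {
  path <- taxid
  while (parent_of[[as.character(taxid)]] != taxid) {
    taxid <- parent_of[[as.character(taxid)]]
    path <- c(taxid, path)
  }
  path
}

bruteLca <- function(taxids, taxid_vec, parent_vec) {
  parent_of <- as.list(stats::setNames(parent_vec, taxid_vec))
  paths <- lapply(unique(taxids), brutePath, parent_of = parent_of)
  common <- Reduce(intersect, paths)
  common[length(common)]
}

# exhaustive PUL rule checker on a role vector using plain loops
brutePulSpans <- function(roles, max_gap) {
  n <- length(roles)
  caz <- which(roles == "cazyme")
  cand <- list()
  # susC/susD pair clause
  for (i in seq_len(max(0, n - 1))) {
    is_pair <- (roles[i] == "susC" && roles[i + 1] == "susD") ||
      (roles[i] == "susD" && roles[i + 1] == "susC")
    if (!is_pair) next
    near <- integer(0)
    for (p in caz) {
      if (p < i && (i - p - 1) <= max_gap) near <- c(near, p)
      if (p > i + 1 && (p - i - 2) <= max_gap) near <- c(near, p)
    }
    if (length(near) >= 2) {
      cand[[length(cand) + 1]] <- c(min(c(i, near)), max(c(i + 1, near)), 1)
    }
  }
  # cazyme chain clause: maximal runs by forward walking
  if (length(caz) >= 3) {
    used <- rep(FALSE, length(caz))
    for (s in seq_along(caz)) {
      if (used[s]) next
      chain <- caz[s]
      cur <- s
      while (cur < length(caz) && caz[cur + 1] - caz[cur] - 1 <= max_gap) {
        cur <- cur + 1
        chain <- c(chain, caz[cur])
        used[cur] <- TRUE
      }
      if (length(chain) >= 3) {
        cand[[length(cand) + 1]] <- c(chain[1], chain[length(chain)], 2)
      }
    }
  }
  if (!length(cand)) return(NULL)
  m <- do.call(rbind, cand)
  # merge any overlapping pair until stable
  repeat {
    merged <- FALSE
    for (a in seq_len(nrow(m) - 1)) {
      for (b in (a + 1):nrow(m)) {
        if (m[a, 1] <= m[b, 2] && m[b, 1] <= m[a, 2]) {
          m[a, ] <- c(min(m[a, 1], m[b, 1]), max(m[a, 2], m[b, 2]),
                      min(m[a, 3], m[b, 3]))
          m <- m[-b, , drop = FALSE]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged || nrow(m) < 2) break
  }
  m[order(m[, 1]), , drop = FALSE]
}

# build an assignRoles-style locus data.frame from a role vector
locusFromRoles <- function(roles, contig = "c1") {
  data.frame(
    gene_id = sprintf("%s_g%02d", contig, seq_along(roles)),
    parent_id = contig,
    ordinal = seq_along(roles) - 1L,
    length_bp = 1000L,
    labels = c(susC = "susC", susD = "susD", cazyme = "GH1",
               other = "hypothetical")[roles],
    is_susC = roles == "susC",
    is_susD = roles == "susD",
    is_cazyme = roles == "cazyme",
    families = ifelse(roles == "cazyme", "GH1", ""),
    role = ifelse(roles == "cazyme", "degradative_cazyme", roles),
    stringsAsFactors = FALSE
  )
}

# random fragmented depth profile (non-overlapping intervals, gaps ok)
randomDepthProfile <- function(genome_length, max_intervals = 30) {
  cuts <- sort(sample(0:genome_length, sample(2:max_intervals, 1)))
  cuts <- unique(c(0, cuts, genome_length))
  out <- data.frame(genome_id = "g",
                    start = utils::head(cuts, -1),
                    end = cuts[-1],
                    depth = sample(0:50, length(cuts) - 1, replace = TRUE))
  # randomly drop some intervals to create gaps (implicit zero depth)
  keep <- runif(nrow(out)) < 0.8
  if (!any(keep)) keep[1] <- TRUE
  out[keep, , drop = FALSE]
}

# compare detectPuls result with oracle spans on a role vector
expectPulAgreement <- function(roles, max_gap = 6L) {
  locus <- locusFromRoles(roles)
  calls <- detectPuls(locus, maxGap = max_gap)
  oracle <- brutePulSpans(roles, max_gap)
  if (is.null(oracle)) {
    expect_identical(nrow(calls), 0L,
                     info = paste(roles, collapse = ","))
  } else {
    got <- cbind(calls$start_ordinal + 1L, calls$end_ordinal + 1L,
                 ifelse(calls$trigger_clause == "susCD_pair", 1L, 2L))
    expect_equal(unname(got[order(got[, 1]), , drop = FALSE]),
                 unname(oracle),
                 info = paste(roles, collapse = ","))
  }
}
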