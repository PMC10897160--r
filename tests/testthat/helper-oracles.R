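# Brute-force reference implementations used to cross-check the package.

# per-base coverage recount aggregated to bins
oracle_coverage <- function(chrom, pos, width, seqlengths, bin_size) {
  lapply(names(seqlengths), function(ctg) {
    n_bins <- as.integer(ceiling(seqlengths[[ctg]] / bin_size))
    v <- integer(n_bins)
    idx <- which(chrom == ctg)
    for (i in idx) {
      b1 <- (pos[i] - 1L) %/% bin_size + 1L
      b2 <- (pos[i] + width[i] - 2L) %/% bin_size + 1L
      b2 <- min(b2, n_bins)
      v[b1:b2] <- v[b1:b2] + 1L
    }
    v
  }) |> setNames(names(seqlengths))
}

# union-find interval merge on one contig
oracle_merge <- function(starts, ends, gap) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  out_s <- starts[1]; out_e <- ends[1]
  res <- list()
  for (i in seq_along(starts)[-1]) {
    if (starts[i] - out_e - 1L <= gap) {
      out_e <- max(out_e, ends[i])
    } else {
      res[[length(res) + 1L]] <- c(out_s, out_e)
      out_s <- starts[i]; out_e <- ends[i]
    }
  }
  res[[length(res) + 1L]] <- c(out_s, out_e)
  do.call(rbind, res)
}

# O(n^2) single-linkage clustering of raw junctions
oracle_cluster <- function(raw, window = 500L, min_support = 2L) {
  n <- nrow(raw)
  linked <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      linked[i, j] <- raw$chrom1[i] == raw$chrom1[j] &&
        raw$chrom2[i] == raw$chrom2[j] &&
        abs(raw$pos1[i] - raw$pos1[j]) <= window &&
        abs(raw$pos2[i] - raw$pos2[j]) <= window
    }
  }
  comp <- rep(NA_integer_, n)
  nc <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    nc <- nc + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- nc
      queue <- c(queue, which(linked[v, ] & is.na(comp)))
    }
  }
  rows <- lapply(split(seq_len(n), comp), function(idx) {
    data.frame(chrom1 = raw$chrom1[idx[1]],
               pos1 = weighted_median(raw$pos1[idx]),
               chrom2 = raw$chrom2[idx[1]],
               pos2 = weighted_median(raw$pos2[idx]),
               support = length(idx))
  })
  out <- do.call(rbind, rows)
  out <- out[out$support >= min_support, , drop = FALSE]
  out <- out[order(out$chrom1, out$pos1, out$chrom2, out$pos2), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# set-arithmetic oracle for the classification equations on one
# pseudo-bulk CPR over toy cells (plain integer position sets)
oracle_classify <- function(pseudo, cells, mito_len, mito_cells,
                            min_overlap = 0.1, f_threshold = 0.65,
                            u_threshold = 0.3) {
  pset <- seq(pseudo[1], pseudo[2])
  need <- min_overlap * length(pset)
  freq <- function(target_set, cell_list, need) {
    pos <- vapply(cell_list, function(ivs) {
      if (length(ivs) == 0) return(FALSE)
      any(vapply(ivs, function(iv) {
        length(intersect(seq(iv[1], iv[2]), target_set)) >= need
      }, logical(1)))
    }, logical(1))
    sum(pos) / length(cell_list)
  }
  jacc <- function(target_set, cell_list) {
    js <- vapply(cell_list, function(ivs) {
      ov <- Filter(function(iv) {
        length(intersect(seq(iv[1], iv[2]), target_set)) > 0
      }, ivs)
      if (length(ov) == 0) return(0)
      a <- unique(unlist(lapply(ov, function(iv) seq(iv[1], iv[2]))))
      length(intersect(a, target_set)) / length(union(a, target_set))
    }, numeric(1))
    mean(js)
  }
  mset <- seq(1L, mito_len)
  f_mt <- freq(mset, mito_cells, min_overlap * mito_len)
  j_mt <- jacc(mset, mito_cells)
  f_raw <- freq(pset, cells, need)
  j_raw <- jacc(pset, cells)
  f_norm <- min(1, f_raw / f_mt)
  j_norm <- min(1, j_raw / j_mt)
  u <- f_norm * j_norm
  label <- paste0(if (f_norm > f_threshold) "HF" else "LF",
                  if (u > u_threshold) "HU" else "LU")
  list(f_raw = f_raw, j_raw = j_raw, f_mt = f_mt, j_mt = j_mt,
       f_norm = f_norm, j_norm = j_norm, u = u, label = label)
}

# exact two-sided rank-sum p value by enumeration of group assignments
oracle_ranksum_p <- function(xa, xb) {
  pooled <- c(xa, xb)
  na <- length(xa)
  r <- rank(pooled)
  obs <- sum(r[seq_len(na)])
  combs <- utils::combn(length(pooled), na)
  stats <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- na * (length(pooled) + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-12)
}
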