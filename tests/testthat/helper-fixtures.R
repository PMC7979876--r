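# in-code fixture builders and independent oracles shared across test files

# one small-variant record that passes every pipeline filter unless a field
# is overridden
makeCall <- function(chrom = "17", pos = 1000L, ref = "A", alt = "T",
                     qual = 30, numalt = 1L, ao = 50L, ro = 50L,
                     saf = 25L, sar = 25L, srf = 25L, srr = 25L,
                     qa = 1500, qr = 1500, mqm = 60, sap = 5, ab = 0.5) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, qual = qual,
             numalt = numalt, ao = ao, ro = ro, saf = saf, sar = sar,
             srf = srf, srr = srr, qa = qa, qr = qr, mqm = mqm, sap = sap,
             ab = ab, stringsAsFactors = FALSE)
}

makeCalls <- function(...) SmallVariantCalls(do.call(rbind, list(...)))

# a random but internally consistent call table (counts satisfy the class
# invariants); used for the idempotence/commutation property tests
randomCalls <- function(n, seed) {
  set.seed(seed)
  depth <- sample(5:150, n, replace = TRUE)
  ao <- vapply(depth, function(d) sample.int(d, 1), integer(1))
  ro <- depth - ao
  saf <- vapply(ao, function(a) sample(0:a, 1), integer(1))
  srf <- vapply(ro, function(r) sample(0:r, 1), integer(1))
  SmallVariantCalls(data.frame(
    chrom = "17", pos = sample.int(1e6, n), ref = "A",
    alt = sample(c("C", "G", "T"), n, replace = TRUE),
    qual = round(runif(n, 0, 60), 1),
    numalt = sample(1:3, n, replace = TRUE, prob = c(0.8, 0.15, 0.05)),
    ao = ao, ro = ro, saf = saf, sar = ao - saf, srf = srf, srr = ro - srf,
    qa = round(ao * runif(n, 5, 25), 1), qr = round(ro * runif(n, 5, 25), 1),
    mqm = round(runif(n, 30, 70), 1), sap = round(runif(n, 0, 60), 1),
    ab = round(ro / pmax(depth, 1), 4), stringsAsFactors = FALSE))
}

makeSv <- function(svtype = "DEL", chrom = "1", start = 1000000L,
                   end = 1100000L, chr2 = chrom, svlen = end - start,
                   precise = TRUE, af = 0.4, source_method = NA_character_,
                   truth_label = "unlabelled") {
  data.frame(svtype = svtype, chrom = chrom, start = start, chr2 = chr2,
             end = end, svlen = svlen, precise = precise, af = af,
             filter_status = "PASS", source_method = source_method,
             truth_label = truth_label, stringsAsFactors = FALSE)
}

makeSvSet <- function(...) SvCallSet(do.call(rbind, list(...)))

snvKeys <- function(x) {
  df <- callTable(x)
  paste(df$chrom, df$pos, df$alt, sep = ":")
}

# independent oracle for the circular split scan: naive double loop over all
# arc pairs, means computed directly with mean()
oracleBestSplit <- function(x, w) {
  n <- length(x)
  best <- -Inf; bi <- NA_integer_; bj <- NA_integer_
  for (i in 0:(n - 1)) {
    for (j in (i + 1):n) {
      k <- j - i; m <- n - k
      if (k < w || m < w) next
      arc <- x[(i + 1):j]
      rest <- x[-((i + 1):j)]
      z <- abs(mean(arc) - mean(rest)) / sqrt(1 / k + 1 / m)
      if (z > best) { best <- z; bi <- i; bj <- j }
    }
  }
  list(stat = best, i = bi, j = bj)
}

# independent clustering oracle: transitive closure of the pairwise match
# predicate via igraph connected components
oracleClusters <- function(df, tol) {
  n <- nrow(df)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      adj[i, j] <- df$svtype[i] == df$svtype[j] &&
        df$chrom[i] == df$chrom[j] && df$chr2[i] == df$chr2[j] &&
        abs(df$start[i] - df$start[j]) <= tol &&
        abs(df$end[i] - df$end[j]) <= tol
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::components(g)$membership
}

# canonical form of a clustering: sorted list of sorted member-key vectors
clusterSignature <- function(membership, keys) {
  sig <- lapply(split(keys, membership), sort)
  unname(sig[order(vapply(sig, `[`, "", 1L))])
}
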