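# Independent brute-force oracles used to verify the package's
# implementations. These deliberately share no code with the package.

# Two-tailed Mann-Whitney p by full enumeration of all C(n+m, n)
# assignments of the pooled values to the first group.
oracleMannWhitneyP <- function(x, y) {
    n <- length(x)
    pool <- c(x, y)
    N <- length(pool)
    uStat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    u0 <- uStat(x, y)
    combs <- combn(N, n)
    us <- apply(combs, 2L, function(i) uStat(pool[i], pool[-i]))
    min(1, mean(us <= min(u0, n * (N - n) - u0)) +
           mean(us >= max(u0, n * (N - n) - u0)))
}

# Benjamini-Hochberg step-up, written directly from the definition:
# q_(i) = min_{j >= i} p_(j) * m / j.
oracleBH <- function(p) {
    m <- length(p)
    ord <- order(p)
    q <- numeric(m)
    prev <- Inf
    for (i in rev(seq_len(m))) {
        prev <- min(prev, p[ord[i]] * m / i)
        q[ord[i]] <- min(1, prev)
    }
    q
}

# Transitive-closure clustering oracle: repeatedly merge any two clusters
# containing positions within `window` bp, then report each cluster's
# modal position (max count, ties -> lowest coordinate) and summed count.
oracleCollapse <- function(positions, counts, window = 100) {
    agg <- tapply(counts, positions, sum)
    pos <- as.integer(names(agg))
    cnt <- as.numeric(agg)
    cluster <- seq_along(pos)
    repeat {
        changed <- FALSE
        for (i in seq_along(pos)) for (j in seq_along(pos)) {
            if (cluster[i] != cluster[j] &&
                abs(pos[i] - pos[j]) <= window) {
                cluster[cluster == cluster[j]] <- cluster[i]
                changed <- TRUE
            }
        }
        if (!changed) break
    }
    out <- do.call(rbind, lapply(unique(cluster), function(cl) {
        i <- which(cluster == cl)
        best <- i[cnt[i] == max(cnt[i])]
        data.frame(position = min(pos[best][pos[best] ==
                       min(pos[best])]), count = sum(cnt[i]))
    }))
    out[order(out$position), , drop = FALSE]
}

# Naive all-offsets, both-strands exact scan of one flank against a
# genome given as a named character vector of chromosome strings.
oracleScan <- function(flank, genomeStrings) {
    rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(flank, "")[[1]]),
                                       collapse = ""))
    hits <- list()
    for (chr in names(genomeStrings)) {
        g <- genomeStrings[[chr]]
        for (s in c("+", "-")) {
            pat <- if (s == "+") flank else rc
            # scan every offset so overlapping occurrences all count
            p <- integer()
            start <- 1L
            repeat {
                hit <- regexpr(pat, substr(g, start, nchar(g)),
                               fixed = TRUE)
                if (hit < 0) break
                p <- c(p, start + hit - 1L)
                start <- start + hit
            }
            if (length(p))
                hits[[length(hits) + 1L]] <- data.frame(
                    chromosome = chr, strand = s, start = p,
                    junction = if (s == "+") p else
                        p + nchar(flank) - 1L)
        }
    }
    if (length(hits)) do.call(rbind, hits) else
        data.frame(chromosome = character(), strand = character(),
                   start = integer(), junction = integer())
}

# Exhaustive adapter-overlap oracle: the truncation point is the first
# position where the remaining read suffix equals a prefix of the
# adapter of length >= minOverlap (or the full adapter occurs).
oracleClip <- function(read, adapter, minOverlap = 8) {
    n <- nchar(read)
    for (s in seq_len(n)) {
        suffix <- substr(read, s, n)
        k <- nchar(suffix)
        if (k < minOverlap) break
        if (k >= nchar(adapter)) {
            if (substr(suffix, 1, nchar(adapter)) == adapter)
                return(substr(read, 1, s - 1))
        } else if (suffix == substr(adapter, 1, k)) {
            return(substr(read, 1, s - 1))
        }
    }
    read
}
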