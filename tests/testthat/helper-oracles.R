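## Independent oracles kept deliberately naive, so they share no code path
## with the implementations they check.

## brute-force recount of completeness / contamination from a copy-count
## vector over the 43-marker grid
oracle_scg <- function(counts) {
    present <- 0; extra <- 0
    for (k in counts) {
        if (k >= 1) present <- present + 1
        if (k > 1) extra <- extra + (k - 1)
    }
    list(completeness = 100 * present / length(counts),
         contamination = 100 * extra / length(counts))
}

## union-find single-linkage oracle over an ANI matrix
oracle_union_find <- function(ani, threshold) {
    n <- nrow(ani)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        if (!is.na(ani[i, j]) && ani[i, j] > threshold) {
            ri <- find(i); rj <- find(j)
            if (ri != rj) parent[rj] <- ri
        }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    split(rownames(ani), roots)
}

## mean-of-means oracle for module completeness
oracle_module_groups <- function(koSets, modules, categories) {
    per_genome <- numeric(0)
    for (g in names(koSets)) {
        fr <- numeric(0)
        for (m in names(modules))
            fr <- c(fr, sum(modules[[m]] %in% koSets[[g]]) /
                        length(modules[[m]]))
        per_genome[g] <- mean(fr)
    }
    out <- numeric(0)
    for (cat in unique(categories)) {
        ids <- names(categories)[categories == cat]
        out[cat] <- mean(per_genome[ids])
    }
    out
}

## canonicalize a clustering (list of member vectors) for comparison
canon_clusters <- function(cl) {
    cl <- lapply(cl, function(x) sort(as.character(x)))
    unname(cl[order(vapply(cl, `[`, character(1), 1L))])
}

random_symmetric_ani <- function(seed, n, lo = 95, hi = 100) {
    set.seed(seed)
    m <- matrix(0, n, n)
    vals <- runif(n * (n - 1) / 2, lo, hi)
    m[upper.tri(m)] <- vals
    m <- m + t(m)
    diag(m) <- 100
    dimnames(m) <- list(sprintf("g%03d", 1:n), sprintf("g%03d", 1:n))
    m
}
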