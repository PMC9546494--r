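# Internal helpers shared across modules.

# Union-find with path halving; n nodes, 1-based ids.
.ufNew <- function(n) seq_len(n)

.ufFind <- function(uf, i) {
  while (uf[i] != i) {
    uf[i] <- uf[uf[i]]
    i <- uf[i]
  }
  i
}

.ufUnion <- function(uf, i, j) {
  ri <- .ufFind(uf, i)
  rj <- .ufFind(uf, j)
  if (ri != rj) uf[rj] <- ri
  uf
}

# Resolve every node to its component root; returns integer component labels.
.ufComponents <- function(uf) {
  roots <- vapply(seq_along(uf), function(i) .ufFind(uf, i), integer(1))
  match(roots, unique(roots))
}

# Evaluate expr with a local RNG seed, restoring global RNG state afterwards.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Character key identifying an intron chain: chrom:strand:s1-e1,s2-e2,...
# Mono-exonic models get chrom:strand: (empty chain).
.chainKeyFromIntrons <- function(chrom, strand, starts, ends) {
  paste0(chrom, ":", strand, ":", paste(starts, ends, sep = "-", collapse = ","))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Junction key "chrom:strand:start-end" for a GRanges; length-0 safe.
.sjKey <- function(g) {
  if (length(g) == 0L) return(character(0))
  paste0(as.character(GenomicRanges::seqnames(g)), ":",
         as.character(BiocGenerics::strand(g)), ":",
         BiocGenerics::start(g), "-", BiocGenerics::end(g))
}
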