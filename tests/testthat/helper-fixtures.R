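# Fixture builders shared across test files. Everything is generated in
# code; nothing binary is read from disk.

makeProfile <- function(five, three, molecule = "18S", sample = "s1") {
  new("EndCountProfile", moleculeId = molecule, sampleId = sample,
      fivePrime = as.integer(five), threePrime = as.integer(three))
}

combinedProfile <- function(combined, molecule = "18S", sample = "s1") {
  p <- makeProfile(integer(length(combined)), integer(length(combined)),
                   molecule, sample)
  p@combined <- as.numeric(combined)
  p
}

writeTestFasta <- function(records, path = tempfile(fileext = ".fa")) {
  writeLines(unlist(lapply(names(records), function(n)
    c(paste0(">", n), records[[n]]))), path)
  path
}

# A SAM file with given alignment rows over one reference.
writeTestSam <- function(rows, refName, refLen,
                         path = tempfile(fileext = ".sam")) {
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", refName, refLen),
               rows), path)
  path
}

samRow <- function(qname, flag, ref, pos, cigar, qlen) {
  sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t*",
          qname, flag, ref, pos, cigar, strrep("A", qlen))
}

# Independent per-read end tally straight off the SAM text: parses flags
# and CIGAR itself, without Rsamtools, to serve as an oracle for
# countReadEnds().
bruteForceEndTally <- function(samPath, refName, refLen) {
  lines <- readLines(samPath)
  lines <- lines[!startsWith(lines, "@")]
  five <- integer(refLen); three <- integer(refLen)
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) > 0L) next        # unmapped
    if (bitwAnd(flag, 256L) > 0L) next      # secondary
    if (bitwAnd(flag, 2048L) > 0L) next     # supplementary
    if (bitwAnd(flag, 16L) > 0L) next       # reverse strand
    if (f[3] != refName) next
    pos <- as.integer(f[4])
    ops <- regmatches(f[6], gregexpr("[0-9]+[MIDNSHP=X]", f[6]))[[1]]
    span <- 0L
    for (op in ops) {
      n <- as.integer(sub("[A-Z=]$", "", op))
      type <- sub("^[0-9]+", "", op)
      if (type %in% c("M", "D", "N", "=", "X")) span <- span + n
    }
    en <- pos + span - 1L
    if (pos >= 1L && en <= refLen) {
      five[pos] <- five[pos] + 1L
      three[en] <- three[en] + 1L
    }
  }
  list(five = five, three = three)
}

# Small helper for t-test oracle: pooled-variance two-tailed p.
pooledTP <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t <- (mean(b) - mean(a)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), n1 + n2 - 2))
}
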