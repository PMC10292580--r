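# In-silico digestion of a protein FASTA database and the inverted-index
# peptide query ("PIndex"): precursor (m/z bin, charge) -> peptide index set
# (Index1) and fragment m/z bin -> peptide index set (Index2). Cluster-to-
# peptide assignment intersects the two and ranks candidates by hyperscore.

#' Tryptic cleavage of one protein sequence
#'
#' Cleaves after K or R, not before P, with up to `missedCleavages` missed
#' sites.
#'
#' @param sequence protein amino-acid string.
#' @param missedCleavages maximum missed cleavages (default 1).
#' @return character vector of peptides with attribute `nterm` flagging
#'   peptides that start at the protein N-terminus.
#' @export
digestProtein <- function(sequence, missedCleavages = 1) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  if (n == 0L) return(character())
  cut <- which(aa %in% c("K", "R"))
  # no cleavage before proline
  cut <- cut[!(cut < n & aa[pmin(cut + 1L, n)] == "P")]
  bounds <- c(0L, cut[cut < n], n)  # segment ends
  bounds <- unique(bounds)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1L]
  peps <- character()
  isNterm <- logical()
  nSeg <- length(starts)
  for (i in seq_len(nSeg)) {
    for (mc in 0:missedCleavages) {
      j <- i + mc
      if (j > nSeg) break
      peps <- c(peps, paste(aa[starts[i]:ends[j]], collapse = ""))
      isNterm <- c(isNterm, starts[i] == 1L)
    }
  }
  attr(peps, "nterm") <- isNterm
  peps
}

#' In-silico digestion of a FASTA database into peptide entries
#'
#' Performs tryptic digestion (cleave after K/R, not before P), applies fixed
#' carbamidomethyl on cysteine, optional variable oxidation on methionine and
#' protein N-terminal acetylation, enumerates precursor charge states, and
#' computes singly charged b/y fragment m/z for every entry. Each entry
#' receives a unique integer index used by the inverted tables.
#'
#' @param fasta path to a protein FASTA file, or a named character vector of
#'   protein sequences.
#' @param missedCleavages maximum missed cleavages (default 1).
#' @param lengthRange allowed peptide length, default c(7, 50).
#' @param charges precursor charge states to enumerate, default 1:5.
#' @param variableMods logical: enumerate oxidation (M) and N-terminal
#'   acetylation variants (default TRUE; at most one of each per peptide).
#' @param mzRange keep entries whose precursor m/z falls in this range.
#' @return data.frame of peptide entries (one row per
#'   sequence/modification/charge) with columns `index`, `sequence`, `mods`,
#'   `charge`, `precursorMz` and list-columns `fragMz`, `fragType`. Peptides
#'   containing non-standard residues are skipped with a warning.
#' @export
digestFasta <- function(fasta, missedCleavages = 1, lengthRange = c(7, 50),
                        charges = 1:5, variableMods = TRUE,
                        mzRange = c(0, Inf)) {
  if (length(fasta) == 1L && file.exists(fasta)) {
    seqs <- Biostrings::readAAStringSet(fasta)
    prot <- as.character(seqs)
  } else {
    prot <- as.character(fasta)
  }
  if (length(prot) == 0L) {
    return(emptyEntries())
  }
  pepSeq <- character(); pepNterm <- logical()
  for (p in prot) {
    d <- digestProtein(p, missedCleavages)
    pepSeq <- c(pepSeq, d)
    pepNterm <- c(pepNterm, attr(d, "nterm"))
  }
  len <- nchar(pepSeq)
  keep <- len >= lengthRange[1] & len <= lengthRange[2]
  pepSeq <- pepSeq[keep]; pepNterm <- pepNterm[keep]
  dup <- duplicated(paste(pepSeq, pepNterm))
  pepSeq <- pepSeq[!dup]; pepNterm <- pepNterm[!dup]

  bad <- vapply(pepSeq, function(s)
    !all(strsplit(s, "")[[1]] %in% names(.RESIDUE_MASS)), logical(1))
  if (any(bad)) {
    warning(sum(bad), " peptide(s) with non-standard residues skipped")
    pepSeq <- pepSeq[!bad]; pepNterm <- pepNterm[!bad]
  }
  if (length(pepSeq) == 0L) return(emptyEntries())

  rows <- vector("list", length(pepSeq) * 2L)
  ri <- 0L
  for (i in seq_along(pepSeq)) {
    s <- pepSeq[i]
    aa <- strsplit(s, "")[[1]]
    camMods <- ifelse(aa == "C", .MOD_CARBAMIDOMETHYL, 0)
    variants <- list(list(res = camMods, nterm = 0, tag = ""))
    if (variableMods) {
      mpos <- which(aa == "M")
      if (length(mpos)) {  # oxidize the first methionine
        ox <- camMods; ox[mpos[1]] <- ox[mpos[1]] + .MOD_OXIDATION
        variants <- c(variants,
                      list(list(res = ox, nterm = 0,
                                tag = sprintf("Oxidation@M%d", mpos[1]))))
      }
      if (pepNterm[i]) {
        variants <- c(variants,
                      list(list(res = camMods, nterm = .MOD_ACETYL,
                                tag = "Acetyl@Nterm")))
      }
    }
    for (v in variants) {
      frag <- fragmentIons(s, residueMods = v$res, ntermMod = v$nterm)
      mass <- sum(.RESIDUE_MASS[aa]) + .WATER + sum(v$res) + v$nterm
      for (z in charges) {
        mz <- (mass + z * .PROTON) / z
        if (mz < mzRange[1] || mz > mzRange[2]) next
        ri <- ri + 1L
        rows[[ri]] <- list(sequence = s, mods = v$tag, charge = as.integer(z),
                           precursorMz = mz, fragMz = frag$mz,
                           fragType = frag$type)
      }
    }
  }
  rows <- rows[seq_len(ri)]
  if (!length(rows)) return(emptyEntries())
  entries <- data.frame(
    index = seq_len(ri),
    sequence = vapply(rows, `[[`, character(1), "sequence"),
    mods = vapply(rows, `[[`, character(1), "mods"),
    charge = vapply(rows, `[[`, integer(1), "charge"),
    precursorMz = vapply(rows, `[[`, numeric(1), "precursorMz")
  )
  entries$fragMz <- lapply(rows, `[[`, "fragMz")
  entries$fragType <- lapply(rows, `[[`, "fragType")
  entries
}

emptyEntries <- function() {
  e <- data.frame(index = integer(), sequence = character(),
                  mods = character(), charge = integer(),
                  precursorMz = numeric())
  e$fragMz <- list(); e$fragType <- list()
  e
}

#' Build the inverted precursor/fragment index over a digest
#'
#' Registers every peptide entry under its precursor (m/z bin, charge) key
#' and under every fragment m/z bin key, including the +-1 neighbor bins so
#' that tolerance windows spanning a bin boundary still hit. Queries
#' post-filter by exact tolerance, so neighbor registration only needs to
#' cover the tolerance radius (one bin).
#'
#' @param entries digest data.frame from [digestFasta()].
#' @param binsPerMz bins per 1 m/z (default 30, i.e. 1/30 Th resolution).
#' @return A [PeptideIndex-class] object.
#' @export
buildInvertedIndex <- function(entries, binsPerMz = 30) {
  stopifnot(nrow(entries) > 0)
  prec <- new.env(hash = TRUE, parent = emptyenv())
  frag <- new.env(hash = TRUE, parent = emptyenv())
  addKey <- function(env, key, idx) {
    cur <- env[[key]]
    env[[key]] <- if (is.null(cur)) idx else c(cur, idx)
  }
  for (i in seq_len(nrow(entries))) {
    idx <- entries$index[i]
    pb <- floor(entries$precursorMz[i] * binsPerMz)
    for (b in (pb - 1L):(pb + 1L))
      addKey(prec, paste0(b, "/", entries$charge[i]), idx)
    fb <- unique(floor(entries$fragMz[[i]] * binsPerMz))
    fb <- unique(c(fb - 1L, fb, fb + 1L))
    for (b in fb) addKey(frag, as.character(b), idx)
  }
  # dedupe sets once
  for (k in ls(prec)) prec[[k]] <- sort(unique(prec[[k]]))
  for (k in ls(frag)) frag[[k]] <- sort(unique(frag[[k]]))
  new("PeptideIndex", entries = entries, precursorTable = prec,
      fragmentTable = frag, binsPerMz = as.integer(binsPerMz))
}

#' Precursor query (Index1)
#'
#' Returns the indexes of peptide entries whose precursor matches the query
#' m/z (within tolerance) at the same charge. The effective tolerance is
#' `max(tolPpm * mz * 1e-6, tolMz)`.
#'
#' @param index a [PeptideIndex-class].
#' @param mz query precursor m/z (Th).
#' @param charge query charge.
#' @param tolPpm relative tolerance in ppm (default 20).
#' @param tolMz absolute tolerance floor in Th (default 0); raise to one bin
#'   width when the query m/z comes from a binned grid.
#' @return sorted integer vector of peptide indexes (possibly empty).
#' @export
queryPrecursor <- function(index, mz, charge, tolPpm = 20, tolMz = 0) {
  stopifnot(charge >= 1)
  tol <- max(tolPpm * mz * 1e-6, tolMz)
  bins <- floor((mz - tol) * index@binsPerMz):floor((mz + tol) *
                                                      index@binsPerMz)
  cand <- unique(unlist(lapply(bins, function(b)
    index@precursorTable[[paste0(b, "/", as.integer(charge))]])))
  if (is.null(cand)) return(integer())
  hit <- abs(index@entries$precursorMz[cand] - mz) <= tol
  sort(cand[hit])
}

#' Fragment query (Index2)
#'
#' Returns the indexes of peptide entries having at least one theoretical
#' b/y fragment within `tolMz` of the query m/z.
#'
#' @param index a [PeptideIndex-class].
#' @param mz query fragment m/z (Th).
#' @param tolMz absolute tolerance in Th (default 0.03).
#' @return sorted integer vector of peptide indexes (possibly empty).
#' @export
queryFragment <- function(index, mz, tolMz = 0.03) {
  bins <- floor((mz - tolMz) * index@binsPerMz):floor((mz + tolMz) *
                                                        index@binsPerMz)
  cand <- unique(unlist(lapply(bins, function(b)
    index@fragmentTable[[as.character(b)]])))
  if (is.null(cand)) return(integer())
  hit <- vapply(cand, function(k)
    min(abs(index@entries$fragMz[[k]] - mz)) <= tolMz, logical(1))
  sort(cand[hit])
}

#' X!Tandem-style hyperscore
#'
#' `log10(Nb! * Ny! * sum(matched intensities))`; zero when nothing matches.
#' Factorials are capped at 10! to keep scores in a conventional range.
#'
#' @param matchedIntensities intensities of matched fragment peaks.
#' @param Nb,Ny counts of matched b and y ions.
#' @return nonnegative score.
#' @export
hyperscore <- function(matchedIntensities, Nb, Ny) {
  stopifnot(Nb >= 0, Ny >= 0)
  if ((Nb + Ny) == 0L || length(matchedIntensities) == 0L) return(0)
  s <- sum(matchedIntensities)
  if (s <= 0) return(0)
  log10(factorial(min(Nb, 10)) * factorial(min(Ny, 10)) * s)
}

#' Assign a fragment cluster to a peptide
#'
#' Computes Index1 for the candidate precursor and the union of Index2 over
#' the cluster's fragment m/z, intersects them, scores every surviving
#' peptide by hyperscore over the matched fragment apex intensities, and
#' returns the ranked match table.
#'
#' @param index a [PeptideIndex-class].
#' @param precursor list with elements `mz` and `charge` (a candidate
#'   precursor from [deisotope()]).
#' @param clusterFragments list of candidate fragments, each a list with
#'   `mz` and `xic` (see [filterFragmentXics()]).
#' @param tolPpm,tolMzPrecursor precursor match tolerance (ppm / absolute Th
#'   floor).
#' @param tolMzFragment fragment match tolerance in Th (default 0.03).
#' @return data.frame ranked by descending hyperscore with columns `index`,
#'   `sequence`, `mods`, `hyperscore`, `Nb`, `Ny` and list-columns
#'   `matchedFrag` (positions into `clusterFragments`), `matchedType`.
#'   Empty when the Index1/Index2 intersection is empty.
#' @export
matchCluster <- function(index, precursor, clusterFragments,
                         tolPpm = 20, tolMzPrecursor = 0,
                         tolMzFragment = 0.03) {
  stopifnot(length(clusterFragments) > 0)
  idx1 <- queryPrecursor(index, precursor$mz, precursor$charge,
                         tolPpm = tolPpm, tolMz = tolMzPrecursor)
  if (!length(idx1)) return(emptyMatches())
  fragMzs <- vapply(clusterFragments, function(f) f$mz, numeric(1))
  idx2 <- sort(unique(unlist(lapply(fragMzs, function(m)
    queryFragment(index, m, tolMz = tolMzFragment)))))
  cand <- intersect(idx1, idx2)
  stopifnot(all(cand %in% idx1), all(cand %in% idx2))
  if (!length(cand)) return(emptyMatches())

  apex <- vapply(clusterFragments, function(f) max(f$xic), numeric(1))
  res <- lapply(cand, function(k) {
    theo <- index@entries$fragMz[[k]]
    type <- index@entries$fragType[[k]]
    # nearest theoretical ion per observed fragment; one observed fragment
    # per theoretical ion (strongest wins)
    nearest <- vapply(fragMzs, function(m) {
      d <- abs(theo - m)
      j <- which.min(d)
      if (d[j] <= tolMzFragment) j else NA_integer_
    }, integer(1))
    ok <- which(!is.na(nearest))
    if (!length(ok)) return(NULL)
    ord <- ok[order(-apex[ok])]
    keepFirst <- ord[!duplicated(nearest[ord])]
    keep <- sort(keepFirst)
    types <- type[nearest[keep]]
    nb <- sum(types == "b"); ny <- sum(types == "y")
    list(index = k, hyperscore = hyperscore(apex[keep], nb, ny),
         Nb = nb, Ny = ny, matchedFrag = keep, matchedType = types)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) return(emptyMatches())
  out <- data.frame(
    index = vapply(res, `[[`, numeric(1), "index"),
    hyperscore = vapply(res, `[[`, numeric(1), "hyperscore"),
    Nb = vapply(res, `[[`, numeric(1), "Nb"),
    Ny = vapply(res, `[[`, numeric(1), "Ny")
  )
  out$matchedFrag <- lapply(res, `[[`, "matchedFrag")
  out$matchedType <- lapply(res, `[[`, "matchedType")
  out$sequence <- index@entries$sequence[match(out$index,
                                               index@entries$index)]
  out$mods <- index@entries$mods[match(out$index, index@entries$index)]
  # descending score, peptide index breaks ties for determinism
  out[order(-out$hyperscore, out$index), , drop = FALSE]
}

emptyMatches <- function() {
  m <- data.frame(index = integer(), hyperscore = numeric(),
                  Nb = numeric(), Ny = numeric())
  m$matchedFrag <- list(); m$matchedType <- list()
  m$sequence <- character(); m$mods <- character()
  m
}
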