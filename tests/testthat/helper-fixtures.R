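# Shared fixtures and independent oracles for the test suite. Heavy
# artifacts (trained models, the labeled training data) are built once per
# session and cached, so every test file sees the same models.

# --- tiny run builder -------------------------------------------------------

# A minimal SWATH-like run: nCycles duty cycles of one MS1 scan plus one MS2
# scan per window; peak content injected via `ms1Peaks(cycle)` and
# `ms2Peaks(cycle, window)` callbacks returning cbind(mz, intensity).
tinyRun <- function(nCycles = 2, windows = data.frame(lower = c(400, 600,
                                                                800),
                                                      upper = c(600, 800,
                                                                1000)),
                    ms1Peaks = function(c) cbind(500, 100),
                    ms2Peaks = function(c, w) cbind(300 + w, 50)) {
  specs <- list()
  id <- 0L
  nWin <- nrow(windows)
  for (c in seq_len(nCycles)) {
    rt0 <- (c - 1)
    pk <- ms1Peaks(c)
    id <- id + 1L
    specs[[id]] <- DiaSpectrum(id, 1L, rt0, pk[, 1], pk[, 2])
    for (w in seq_len(nWin)) {
      pk <- ms2Peaks(c, w)
      id <- id + 1L
      specs[[id]] <- DiaSpectrum(id, 2L, rt0 + w / (nWin + 1),
                                 pk[, 1], pk[, 2],
                                 windowLower = windows$lower[w],
                                 windowUpper = windows$upper[w])
    }
  }
  DiaRun(specs, windowScheme = windows)
}

# --- independent MGF parser (round-trip oracle) -----------------------------

parseMGF <- function(path) {
  lines <- readLines(path)
  out <- list()
  cur <- NULL
  for (ln in lines) {
    if (ln == "BEGIN IONS") {
      cur <- list(fields = list(), mz = numeric(), intensity = numeric())
    } else if (ln == "END IONS") {
      out[[length(out) + 1L]] <- cur
      cur <- NULL
    } else if (!is.null(cur)) {
      if (grepl("=", ln, fixed = TRUE)) {
        kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
        cur$fields[[kv[1]]] <- paste(kv[-1], collapse = "=")
      } else {
        xy <- as.numeric(strsplit(ln, " ", fixed = TRUE)[[1]])
        cur$mz <- c(cur$mz, xy[1])
        cur$intensity <- c(cur$intensity, xy[2])
      }
    }
  }
  out
}

# --- independent scalar Adam reference --------------------------------------

scalarAdamRef <- function(grads, lr = 0.001, beta1 = 0.9, beta2 = 0.999,
                          eps = 1e-8, theta0 = 0) {
  theta <- theta0; m <- 0; v <- 0
  for (t in seq_along(grads)) {
    g <- grads[t]
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    theta <- theta - lr * mhat / (sqrt(vhat) + eps)
  }
  theta
}

# --- random protein database ------------------------------------------------

randomProteins <- function(n, len = 120, seed = 42) {
  set.seed(seed)
  res <- c("G", "A", "S", "P", "V", "T", "C", "L", "I", "N", "D", "Q", "K",
           "E", "M", "H", "F", "R", "Y", "W")
  p <- vapply(seq_len(n), function(i)
    paste(sample(res, len, replace = TRUE), collapse = ""), character(1))
  names(p) <- paste0("prot", seq_len(n))
  p
}

# --- untrained models for shape/determinism tests ---------------------------

untrainedVae <- function(arch = vaeArchitecture(), seed = 1) {
  methods::new("VaeModel", params = initVaeParams(arch, seed = seed),
               arch = arch, config = list(dropP = 0.2), history = numeric())
}

untrainedCnn <- function(channels = 4, fcDim = 16, seed = 1) {
  methods::new("CnnModel",
               params = initCnnParams(channels, fcDim, seed = seed),
               config = list(), history = numeric())
}

# Small two-protein index shared by matching tests.
miniIndex <- function() cached("miniIndex", function() {
  e <- digestFasta(c(a = "GGGLVNELTEFAKDDDR", b = "SSSFEQLHSTVKDDDR"),
                   charges = 2, variableMods = FALSE)
  buildInvertedIndex(e)
})

# --- session cache for heavy artifacts --------------------------------------

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixtureCache[[key]])) .fixtureCache[[key]] <- builder()
  .fixtureCache[[key]]
}

# Training-scale synthetic run (many peptides) and its fragment XIC truth.
trainingXics <- function() cached("trainingXics", function() {
  sim <- simConfig(nPeptides = 60, nCycles = 60, seed = 101)
  sr <- simulateRun(sim)
  list(sr = sr, xics = truthFragmentXics(sr$run, sr$truth))
})

# VAE trained at the study scale: 20,000 triplets, 5 epochs.
trainedVaeModel <- function() cached("vae", function() {
  tx <- trainingXics()
  tri <- makeTriplets(tx$xics, 20000, seed = 202)
  trainVae(tri, epochs = 5, batchSize = 256, seed = 303)
})

# CNN trained on 2,000 labeled groups, 12 epochs, Adam defaults.
trainedCnnModel <- function() cached("cnn", function() {
  tx <- trainingXics()
  gm <- makeGroupMatrices(tx$xics, 2000, seed = 404)
  trainCnn(gm$groups, gm$labels, epochs = 12, seed = 505)
})

# A 20-peptide evaluation run from a FASTA-backed database, for the
# end-to-end recovery tests, plus its pipeline result.
evalScenario <- function() cached("evalScenario", function() {
  prots <- randomProteins(30, seed = 42)
  sim <- simConfig(nPeptides = 20, seed = 7)
  sr <- suppressWarnings(simulateRun(sim, fasta = prots))
  list(prots = prots, sr = sr)
})

pipelineResult <- function() cached("pipelineResult", function() {
  sc <- evalScenario()
  cfg <- pipelineConfig(seed = 1, runName = "eval")
  mgf <- file.path(tempdir(), "eval.mgf")
  rep <- runPipeline(sc$sr$run, sc$prots, trainedVaeModel(),
                     trainedCnnModel(), cfg, mgfPath = mgf)
  list(rep = rep, mgf = mgf, cfg = cfg)
})

# Identical re-execution of the evaluation pipeline (determinism checks).
pipelineRerun <- function() cached("pipelineRerun", function() {
  sc <- evalScenario()
  pr <- pipelineResult()
  mgf <- file.path(tempdir(), "eval_rerun.mgf")
  rep <- runPipeline(sc$sr$run, sc$prots, trainedVaeModel(),
                     trainedCnnModel(), pr$cfg, mgfPath = mgf)
  list(rep = rep, mgf = mgf)
})
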