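# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# Noiseless default phantom rendered at the default imaging grid.
noiselessStudy <- function() fixture("noiselessStudy", function()
  renderCineStudy(phantomSpec(noiseSd = 0), imagingParams()))

# A posed (rotated + translated) noiseless phantom.
posedStudy <- function() fixture("posedStudy", function() {
  pose <- lvatlas:::rigidTransform(lvatlas:::rotationMatrix(c(1, 1, 0), 0.2),
                                   c(10, -20, 30))
  renderCineStudy(phantomSpec(noiseSd = 0, pose = pose), imagingParams())
})

# Small rendered benchmark population for network sanity tests.
tinyPopulation <- function() fixture("tinyPopulation", function()
  benchmarkPopulation(60, seed = 101))

randomGeometry <- function() {
  ax <- lvatlas:::unitv(rnorm(3))
  R <- lvatlas:::rotationMatrix(ax, runif(1, -pi, pi))
  sliceGeometry(origin = runif(3, -100, 100), rowDir = R[, 1], colDir = R[, 2],
                pixelSpacing = runif(2, 0.5, 3))
}
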