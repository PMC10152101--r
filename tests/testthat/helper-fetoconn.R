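## Shared fixtures, all built in code.

## Reported left middle-occipital thalamocortical trajectory parameters
## (span, baseline, inflection week, growth-rate scale).
table1MogL <- c(beta1 = 0.3587, beta2 = -0.0133,
                beta3 = 29.3857, beta4 = 0.4614)

fullParc <- defaultParcellation()
tinyParc <- toyParcellation(4)

## Mirror-symmetric configuration (no decay, no laterality).
symConfig <- list(homologDecay = 0, lateralityOffset = 0,
                  lateralitySlope = 0)
## Stationary null: no age effect of any kind.
nullConfig <- c(symConfig, list(growth = FALSE))

defaultTruth <- buildGroundTruth(fullParc, seed = 1)
symTruth <- buildGroundTruth(fullParc, symConfig, seed = 1)

## Random SPD matrix of dimension n.
randomSpd <- function(n, seed = 1) {
  withSeed(seed, {
    A <- matrix(rnorm(n * n), n)
    crossprod(A) / n + diag(n)
  })
}

## Hemisphere-swap permutation of a node matrix (thalamus fixed).
swapHemispheres <- function(M, parcellation) {
  h <- homologMap(parcellation)
  M[h, h]
}
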