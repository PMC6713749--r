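# Shared fixtures, memoised so the expensive phantom pipeline is built once
# per test run.
fixture_env <- new.env(parent = emptyenv())

# Analysis configuration used for phantom-scale matching: the template
# search radius covers the phantom's peak displacement (~5 voxels) while
# staying below the tag period, so periodic-texture ambiguity cannot enter
# at template level.
phantom_params <- function(...) {
  hierarchy_params(t = 16L, search_radius = 6L, ...)
}

phantom_fixture <- function() {
  if (is.null(fixture_env$phantom)) {
    spec <- phantom_spec()
    truth <- make_deformation(spec)
    vols <- render_frames(spec, truth)
    fixture_env$phantom <- list(spec = spec, truth = truth, vols = vols)
  }
  fixture_env$phantom
}

# Full tracking + strain pipeline on the default cardiac phantom.
pipeline_fixture <- function() {
  if (is.null(fixture_env$pipeline)) {
    ph <- phantom_fixture()
    params <- phantom_params()
    tracking <- suppressWarnings(track_sequence(ph$vols, params, n = 100))
    mesh <- phantom_mesh(ph$spec)
    strain <- strain_pipeline(tracking, mesh)
    fixture_env$pipeline <- list(tracking = tracking, mesh = mesh,
                                 strain = strain, params = params)
  }
  fixture_env$pipeline
}

# Definitional NCC: explicit triple sum over voxels (the oracle the fast
# implementation is checked against).
ncc_triple_sum <- function(block, region, lag) {
  d <- dim(block)
  patch <- region[lag[1] + seq_len(d[1]), lag[2] + seq_len(d[2]),
                  lag[3] + seq_len(d[3])]
  mb <- mean(block)
  mf <- mean(patch)
  num <- 0; vb <- 0; vf <- 0
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    db <- block[x, y, z] - mb
    df <- patch[x, y, z] - mf
    num <- num + db * df
    vb <- vb + db^2
    vf <- vf + df^2
  }
  if (vb == 0 || vf == 0) return(0)
  num / sqrt(vb * vf)
}

# Integer-shift an array, filling vacated voxels with `fill`.
shift_volume <- function(arr, d, fill = 0) {
  dims <- dim(arr)
  out <- array(fill, dims)
  src <- lapply(1:3, function(k) {
    s <- seq_len(dims[k]) - d[k]
    list(dst = which(s >= 1 & s <= dims[k]),
         src = s[s >= 1 & s <= dims[k]])
  })
  out[src[[1]]$dst, src[[2]]$dst, src[[3]]$dst] <-
    arr[src[[1]]$src, src[[2]]$src, src[[3]]$src]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Overwrite the sub-block of `region` at 0-based offset `lag` with `block`.
replace_block <- function(region, block, lag) {
  d <- dim(block)
  region[lag[1] + seq_len(d[1]), lag[2] + seq_len(d[2]),
         lag[3] + seq_len(d[3])] <- block
  region
}

# Random symmetric 3x3 matrix
random_symmetric <- function() {
  a <- matrix(stats::rnorm(9), 3, 3)
  (a + t(a)) / 2
}
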