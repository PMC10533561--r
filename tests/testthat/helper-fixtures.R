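# Shared fixtures: one small simulated plate, reused across test files.
# Everything is generated in code under fixed seeds; no stored data.

fixture_config <- function(...) hyb_config(...)

# 2 parents x (2 bio + 1 tech) = 6 wells; cached per session
.fixture_env <- new.env(parent = emptyenv())

fixture_plate <- function(error_rate = 0, aberrant_fraction = 0.3,
                          depth = 40, n_clones = 2, extra_light = integer(0)) {
  key <- paste(error_rate, aberrant_fraction, depth, n_clones,
               paste(extra_light, collapse = ","), sep = "|")
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  cfg <- fixture_config()
  clones <- make_reference_set(n_clones, seed = 101,
                               extra_light_clones = extra_light,
                               config = cfg)
  spec <- make_plate_spec(clones, n_bio = 2, n_tech = 1, depth = depth,
                          error_rate = error_rate,
                          aberrant_fraction = aberrant_fraction,
                          seed = 202, config = cfg)
  prefix <- tempfile("plate")
  sim <- simulate_plate(spec, prefix)
  out <- list(cfg = cfg, clones = clones, spec = spec, sim = sim,
              prefix = prefix)
  .fixture_env[[key]] <- out
  out
}

# a valid annotated light-chain interior for one clone
fixture_interior <- function(clone, chain = "kappa", cfg = fixture_config()) {
  nt <- if (chain == "heavy") clone$vh_nt else clone$vl_nt
  pad <- cfg$const_pads[[chain]]
  paste0(cfg$utr, nt, pad)
}

# simple flat-quality read list for merge tests
read_of <- function(seq, q = 30L) list(seq = seq, qual = rep(q, nchar(seq)))
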