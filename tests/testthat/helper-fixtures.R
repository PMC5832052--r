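# Shared fixtures, built once per test session. The default phantom is the
# package's reference study condition; the trained model is reused by the
# classifier, pipeline and acceptance tests.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, builder(), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

default_phantom <- function() {
  fixture("default_phantom", function() {
    ph <- render_phantom(phantom_spec(seed = 7))
    ph$smoothed <- anisotropic_diffusion(ph$volume)
    ph
  })
}

training_dataset <- function() {
  fixture("training_dataset", function() {
    ph <- default_phantom()
    build_dataset(ph$smoothed, ph$truth$lung, ph$truth$injured,
                  n_per_class = 1000, seed = 3)
  })
}

trained_model <- function() {
  fixture("trained_model", function() {
    train_injury_ann(training_dataset(), seed = 11)
  })
}

# a tiny all-lung volume of uniformly random HU for feature-oracle checks
random_feature_volume <- function(seed = 42, dim = c(10, 40, 40)) {
  set.seed(seed)
  vol <- ct_volume(array(stats::runif(prod(dim), -1000, 100), dim = dim),
                   spacing_mm = c(1.25, 0.7, 0.7), scan_id = "random")
  lung <- binary_mask(array(TRUE, dim = dim), role = "lung",
                      spacing_mm = vol$spacing_mm)
  list(volume = vol, lung = lung)
}

# independent direct-formula feature evaluation at one pixel (test oracle,
# written against the definitions, not the package internals)
oracle_features <- function(vox, bits, center, edge = 7, thr = -825) {
  dm <- dim(vox)
  win_vals <- function(s, r, cc) {
    h <- (edge - 1) / 2
    out <- c()
    for (i in max(1, r - h):min(dm[2], r + h)) {
      for (j in max(1, cc - h):min(dm[3], cc + h)) {
        if (bits[s, i, j]) out <- c(out, vox[s, i, j])
      }
    }
    out
  }
  v <- win_vals(center[1], center[2], center[3])
  n <- length(v)
  m <- sum(v) / n
  m2 <- sum((v - m)^2) / n
  m3 <- sum((v - m)^3) / n
  m4 <- sum((v - m)^4) / n
  s <- center[1]
  sp <- if (s > 1) s - 1 else s + 1
  sn <- if (s < dm[1]) s + 1 else s - 1
  mprev <- win_vals(sp, center[2], center[3])
  mnext <- win_vals(sn, center[2], center[3])
  mp <- if (length(mprev)) mean(mprev) else m
  mn <- if (length(mnext)) mean(mnext) else m
  list(
    center_hu = vox[center[1], center[2], center[3]],
    mean = m,
    sd = if (n > 1) sqrt(sum((v - m)^2) / (n - 1)) else 0,
    max = max(v), min = min(v),
    skewness = if (m2 > 1e-6) m3 / m2^1.5 else 0,
    kurtosis = if (m2 > 1e-6) m4 / m2^2 - 3 else 0,
    rco = (m - mp) * (m - mn),
    air_fraction = sum(v < thr) / n,
    n_valid = n
  )
}

# brute-force pairwise concordance (Mann-Whitney AUC)
concordance_auc <- function(scores, truth) {
  pos <- scores[truth]
  neg <- scores[!truth]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
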