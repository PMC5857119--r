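# Planted-model simulation: a known (amino acid, ion, octant) generative
# distribution from which training structures and held-out labelled sites
# are sampled, so the predictor can be checked for parameter recovery.

#' A planted generative model of ion environments
#'
#' Each ion type is assigned a small set of signature amino acids that
#' carry most of its neighbor probability, and one preferred octant per
#' (signature aa, ion) pair holding most of the angular mass. Consecutive
#' ions share their signature amino acids in pairs, so aa-composition
#' alone cannot fully separate them — the octant-resolved predictor has
#' to, which is exactly what the recovery check exercises.
#'
#' @param ions Candidate ion labels.
#' @param n_signature Signature amino acids per ion.
#' @param aa_weight Total probability on the signature set (rest uniform
#'   over the other amino acids).
#' @param octant_weight Probability on the preferred octant (rest uniform
#'   over the other seven).
#' @return An object of class `planted_model` with per-ion amino-acid
#'   probabilities and per-(aa, ion) preferred octants.
#' @export
planted_model <- function(ions = default_ion_candidates(),
                          n_signature = 2L, aa_weight = 0.8,
                          octant_weight = 0.9) {
  stopifnot(aa_weight > 0, aa_weight <= 1,
            octant_weight > 0, octant_weight <= 1)
  k <- length(ions)
  aa_prob <- matrix((1 - aa_weight) / (20 - n_signature), nrow = 20, ncol = k,
                    dimnames = list(AA3, ions))
  pref_oct <- matrix(NA_integer_, nrow = 20, ncol = k,
                     dimnames = list(AA3, ions))
  for (j in seq_len(k)) {
    # ions 2m-1 and 2m share signature amino acids but differ in octant
    block <- (ceiling(j / 2) - 1L)
    sig <- AA3[(block * n_signature + seq_len(n_signature) - 1L) %% 20 + 1L]
    aa_prob[, j] <- (1 - aa_weight) / (20 - n_signature)
    aa_prob[sig, j] <- aa_weight / n_signature
    pref_oct[, j] <- (j - 1L) %% 8L
  }
  structure(list(ions = ions, aa_prob = aa_prob, pref_octant = pref_oct,
                 octant_weight = octant_weight),
            class = "planted_model")
}

# draw one (aa, octant, r, theta, phi) environment for an ion
draw_environment <- function(model, ion) {
  aa <- sample(AA3, 1L, prob = model$aa_prob[, ion])
  oct <- model$pref_octant[aa, ion]
  if (runif(1) > model$octant_weight) oct <- sample(setdiff(0:7, oct), 1L)
  # uniform direction within the octant: unsigned components, signs by octant
  u <- abs(stats::rnorm(3))
  u <- u / sqrt(sum(u^2))
  sgn <- c(if (bitwAnd(oct, 4L) > 0) -1 else 1,
           if (bitwAnd(oct, 2L) > 0) -1 else 1,
           if (bitwAnd(oct, 1L) > 0) -1 else 1)
  cart <- runif(1, 2.5, 5.5) * u * sgn
  r <- sqrt(sum(cart^2))
  list(aa = aa, octant = oct, r = r,
       theta = acos(cart[3] / r), phi = atan2(cart[2], cart[1]))
}

# place a residue so the point `q` has local coords (r, theta, phi):
# draw a random orientation, then solve for the translation
residue_at_local <- function(aa, q, r, theta, phi, chain = "A", resno = 1L) {
  rot <- random_rotation(1L)[[1]]
  tpl <- make_residue(aa, rotation = rot, chain = chain, resno = resno)
  frame <- build_frame(tpl)
  target <- place_ion(frame, r, theta, phi)[1, ]
  shift <- q - target
  mutate(tpl, x = .data$x + shift[1], y = .data$y + shift[2],
         z = .data$z + shift[3])
}

#' Sample training structures from a planted model
#'
#' Generates, per ion type, `n_per_ion` independent single-residue sites
#' (residue orientation uniform over rotations, ion planted at the drawn
#' local position) laid out on a coarse grid inside one structure per ion,
#' far enough apart that sites cannot cross-pair at the 6 A cutoff.
#'
#' @param model A `planted_model`.
#' @param n_per_ion Training pairs per ion type.
#' @return A list of `ion_structure` objects, one per ion.
#' @export
simulate_training <- function(model, n_per_ion = 500L) {
  lapply(model$ions, function(io) {
    residues <- vector("list", n_per_ion)
    ion_rows <- vector("list", n_per_ion)
    for (i in seq_len(n_per_ion)) {
      q <- 50 * c(i %% 25L, (i %/% 25L) %% 25L, i %/% 625L)
      env <- draw_environment(model, io)
      residues[[i]] <- residue_at_local(env$aa, q, env$r, env$theta,
                                        env$phi, resno = i)
      ion_rows[[i]] <- tibble(ion = io, x = q[1], y = q[2], z = q[3])
    }
    make_structure(residues, bind_rows(ion_rows),
                   source_id = paste0("TRN-", ion_label_to_code(io)))
  })
}

#' Sample labelled evaluation sites from a planted model
#'
#' Each site is one small structure: `residues_per_site` residues drawn
#' from the model around a single ion of a cycled true type.
#'
#' @param model A `planted_model`.
#' @param n_sites Number of sites.
#' @param residues_per_site Residues surrounding each site.
#' @return A tibble with list-column `structure` and columns `x`, `y`,
#'   `z`, `true_ion`, directly consumable by [evaluate_sites()].
#' @export
simulate_sites <- function(model, n_sites = 200L, residues_per_site = 2L) {
  rows <- lapply(seq_len(n_sites), function(i) {
    io <- model$ions[(i - 1L) %% length(model$ions) + 1L]
    q <- c(0, 0, 0)
    residues <- lapply(seq_len(residues_per_site), function(j) {
      env <- draw_environment(model, io)
      residue_at_local(env$aa, q, env$r, env$theta, env$phi, resno = j)
    })
    st <- make_structure(residues, tibble(ion = io, x = q[1], y = q[2],
                                          z = q[3]),
                         source_id = sprintf("SITE%04d", i))
    tibble(structure = list(st), x = q[1], y = q[2], z = q[3], true_ion = io)
  })
  bind_rows(rows)
}
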