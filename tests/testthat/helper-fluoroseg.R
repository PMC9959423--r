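# Shared fixtures, built in code.

# Well-separated color preset: same class means as the default model,
# tighter channel noise, for parameter-recovery tests where the class
# structure should dominate sampling noise.
separated_model <- function() class_color_model(sd = 0.01)

# Minimal 6-D prototype set with one prototype per class, placed at the
# feature-space images of the default class color means.
class_mean_prototypes <- function(model = class_color_model()) {
  prototype_set(
    make_feature_vector(model$means[, 1], model$means[, 2],
                        model$means[, 3]),
    class_labels())
}

# Small labeled pixel sample at desk scale.
small_pixels <- function(n = c(400, 400, 200, 100, 180),
                         model = class_color_model(), seed = 2) {
  sample_labeled_pixels(n_per_class = n, model = model, seed = seed)
}

# Deterministic flat-color image: every pixel the given RGB triple.
flat_image <- function(rgb, h = 8, w = 10) {
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- rgb[ch]
  img
}

# Hue from the classical arccos HSI formulation (independent oracle).
acos_hue <- function(r, g, b) {
  num <- 0.5 * ((r - g) + (r - b))
  den <- sqrt((r - g)^2 + (r - b) * (g - b))
  th <- acos(pmin(pmax(num / den, -1), 1))
  ifelse(b <= g, th, 2 * pi - th)
}
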