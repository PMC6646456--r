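# Fixtures are built in code: tiny in-memory projects, random multi-label
# grids, a cylinder phantom, and deterministic toy networks.

make_project <- function(rois = c("kidney", "tumor"), shape = c(10, 10, 10),
                         image = NULL, exclusive = FALSE) {
  p <- project_create(exclusive_mode = exclusive)
  for (r in rois) define_roi(p, r)
  img <- image %||% array(0, shape)
  add_series(p, "s1", image = img)
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_mask <- function(shape, p = 0.3) {
  array(stats::runif(prod(shape)) < p, shape)
}

# label volume carrying a given logical mask on bit 1
mask_lv <- function(mask) {
  lv <- label_volume(dim(mask))
  lv$labels[mask] <- 1
  lv
}

cylinder_image <- function(shape = c(32, 32, 16), zrange = 4:13, radius = 8,
                           fg = 100, sigma = 5, seed = 5) {
  set.seed(seed)
  img <- array(stats::rnorm(prod(shape), 0, sigma), shape)
  truth <- array(FALSE, shape)
  cx <- shape[1] / 2; cy <- shape[2] / 2
  for (z in zrange) {
    for (i in seq_len(shape[1])) for (j in seq_len(shape[2]))
      if ((i - cx)^2 + (j - cy)^2 <= radius^2) truth[i, j, z] <- TRUE
  }
  img[truth] <- img[truth] + fg
  list(image = img, truth = truth)
}

# toy classifier: conv -> conv -> gap -> linear dense (CAM architecture)
cam_toynet <- function(seed = 2, in_dim = 6, classes = 3) {
  set.seed(seed)
  toynet(list(
    list(type = "conv2d", W = array(rnorm(3 * 3 * 1 * 2, sd = 0.5),
                                    c(3, 3, 1, 2)),
         b = c(0.1, -0.2), activation = "relu"),
    list(type = "conv2d", W = array(rnorm(3 * 3 * 2 * 3, sd = 0.5),
                                    c(3, 3, 2, 3)),
         b = rep(0, 3), activation = "relu"),
    list(type = "gap"),
    list(type = "dense", W = matrix(rnorm(3 * classes), 3, classes),
         b = rep(0, classes), activation = "linear")
  ), input_shape = c(in_dim, in_dim, 1))
}

# 1x1-conv "threshold network": argmax(class scores) == 1[x > cut]
threshold_net <- function(cut = 0.5, gain = 1000) {
  toynet(list(list(type = "conv2d",
                   W = array(c(-gain, gain), c(1, 1, 1, 2)),
                   b = c(cut * gain, -cut * gain), activation = "linear")),
         input_shape = c(32, 32, 1))
}

three_pool_workflow <- function() {
  parse_workflow("
users:
  analyst1: analyst
  analyst2: analyst
  reviewer1: reviewer
  scientist1: scientist
pools: [analyst, reviewer, scientist]
initial_pool: analyst
rights:
  analyst:
    may_acquire_from: [analyst]
    may_assign_to: [analyst, reviewer]
  reviewer:
    may_acquire_from: [reviewer]
    may_assign_to: [analyst, scientist]
    may_assign_to_users: [analyst1]
  scientist:
    may_acquire_from: [scientist]
    may_assign_to: [scientist]
")
}
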