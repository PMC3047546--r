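# shared fixtures, all built in code

tiny_records <- function() {
  plot_data(data.frame(
    site = c("A", "A", "B", "B"),
    block = c("1", "1", "1", "2"),
    plot = c("p1", "p2", "p3", "p4"),
    richness = c(1L, 2L, 1L, 2L),
    composition = c("m1", "x1", "m1", "x1"),
    anpp = c(100, 150, 120, 180)
  ))
}

# balanced one-way layout expressed in the canonical schema: groups are
# composition codes, one site, one block
oneway_records <- function(y, groups) {
  rec <- plot_data(data.frame(
    site = "S", block = "1", plot = paste0("p", seq_along(y)),
    richness = 1L, composition = paste0("g", groups), anpp = y),
    nonneg_anpp = FALSE)
  rec$composition_code <- as.integer(factor(groups))
  rec
}

# small 4-site design for fast model fits (128 plots)
small_design <- function() {
  lapply(1:4, function(i)
    list(site = paste0("S", i), blocks = 2L, richness = c(1L, 2L, 4L, 8L),
         n_comps = 8L, n_plots = 32L))
}

small_skeleton <- function(seed = 1L)
  build_skeleton(small_design(), sharing_fraction = 0.5, seed = seed)

small_sim <- function(seed = 1L, skeleton = small_skeleton()) {
  simulate_responses(skeleton, default_truth(skeleton), seed = seed)
}

# two-batch toy for likelihood-ratio simulations: block effects plus
# grouped (composition) effects plus noise
lrt_toy <- function(sd_group, n_groups = 15L, n_rep = 4L, sd_block = 20,
                    sd_noise = 30, seed = 1L) {
  set.seed(seed)
  grp <- rep(seq_len(n_groups), each = n_rep)
  blk <- rep_len(1:2, n_groups * n_rep)
  y <- stats::rnorm(2, 0, sd_block)[blk] +
    stats::rnorm(n_groups, 0, sd_group)[grp] +
    stats::rnorm(n_groups * n_rep, 0, sd_noise)
  rec <- plot_data(data.frame(
    site = "S", block = blk, plot = seq_along(y), richness = 1L,
    composition = paste0("g", grp), anpp = y), nonneg_anpp = FALSE)
  rec$composition_code <- grp
  rec
}
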