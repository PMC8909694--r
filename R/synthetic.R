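#' Generate a synthetic regulatory dataset with planted structure
#'
#' Emulates the statistical structure the modelling pipeline assumes, so
#' every stage can be exercised end to end without external data:
#'
#' 1. each TF `t` gets a latent per-sample activity `a_t ~ N(0, 1)`; TFs in
#'    the planted indirect module share a common factor with loading
#'    `sqrt(module_correlation)` (residual loading scaled so the variance
#'    stays 1), which makes their activities densely correlated; the same
#'    factor drives a fraction `indirect_drive` of each planted direct TF's
#'    activity variance, the path by which indirect regulation reaches the
#'    target;
#' 2. each TF's target genes are `a_t` plus independent Gaussian noise
#'    (`target_noise_sd`), so the activity statistic approximately recovers
#'    `a_t` from the expression matrix;
#' 3. the target gene is `beta0 + sum_t beta_t * es_t * a_t + N(0, noise_sd)`
#'    per condition, using that condition's planted direct-regulator set;
#' 4. the coding gene of each planted direct regulator additionally tracks
#'    the mean activity of the planted indirect TFs wired onto it, so the
#'    indirect pre-selection stage has signal to find;
#' 5. missing values are sprinkled uniformly at rate `na_frac`.
#'
#' The network contains every TF's edges onto its own target genes, an edge
#' from every TF onto the target gene (so all TFs are candidate direct
#' regulators, as promoter-binding databases would report), edges from planted
#' indirect TFs onto the planted direct TFs' coding genes and onto each other
#' (a cross-regulating TF cluster), plus a few random background TF-TF edges.
#'
#' @param n_tfs Number of TFs (named `TF01`, `TF02`, ...).
#' @param n_targets_per_tf Targets per TF (default 5).
#' @param n_samples_a,n_samples_b Samples per condition (labels `"A"`,
#'   `"B"`).
#' @param planted_direct_a,planted_direct_b Named numeric vectors: planted
#'   regression coefficients (`beta`) per condition, names are TF ids.
#' @param planted_indirect Character vector of TF ids forming the planted
#'   correlated module (default none).
#' @param module_correlation Shared-factor variance fraction within the
#'   planted module, in (0, 1) (default 0.8).
#' @param indirect_drive Fraction of each planted direct TF's activity
#'   variance driven by the module's shared factor (default 0.5; only used
#'   when a module is planted). This is how indirect regulation reaches the
#'   target: the module regulates the direct regulators, which regulate the
#'   target.
#' @param noise_sd Gaussian noise SD on the target gene (default 0.5).
#' @param target_noise_sd Noise SD on TF target genes (default 0.5).
#' @param na_frac Missing-value rate (default 0).
#' @param beta0 Intercept of the planted model (default 0).
#' @param target_gene Id of the modelled gene (default `"TG"`).
#' @param seed Integer seed; identical seeds give identical output.
#' @return List with `expression` (`expr_matrix`), `network`
#'   (`reg_network`) and `truth` (planted sets, coefficients, latent
#'   activities and all parameters).
#' @export
simulate_regulation <- function(n_tfs = 20, n_targets_per_tf = 5,
                                n_samples_a = 200, n_samples_b = 200,
                                planted_direct_a = c(TF01 = 1, TF02 = 1),
                                planted_direct_b = planted_direct_a,
                                planted_indirect = character(),
                                module_correlation = 0.8, indirect_drive = 0.5,
                                noise_sd = 0.5,
                                target_noise_sd = 0.5, na_frac = 0,
                                beta0 = 0, target_gene = "TG", seed = 1) {
  stopifnot(n_tfs >= 1, n_targets_per_tf >= 1, n_samples_a >= 1,
            n_samples_b >= 0, noise_sd >= 0, na_frac >= 0, na_frac < 1,
            module_correlation > 0, module_correlation < 1,
            indirect_drive >= 0, indirect_drive < 1)
  tfs <- sprintf("TF%02d", seq_len(n_tfs))
  bad <- setdiff(c(names(planted_direct_a), names(planted_direct_b),
                   planted_indirect), tfs)
  if (length(bad)) {
    stop("planted regulator(s) outside the TF set: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  n <- n_samples_a + n_samples_b
  samples <- sprintf("S%03d", seq_len(n))
  condition <- stats::setNames(rep(c("A", "B"), c(n_samples_a, n_samples_b)),
                               samples)

  withr::with_seed(seed, {
    # latent activities; planted-module TFs share a common factor
    act <- matrix(stats::rnorm(n_tfs * n), nrow = n_tfs,
                  dimnames = list(tfs, samples))
    if (length(planted_indirect) >= 2L) {
      common <- stats::rnorm(n)
      lo <- sqrt(module_correlation)
      act[planted_indirect, ] <-
        lo * rep(common, each = length(planted_indirect)) +
        sqrt(1 - module_correlation) * act[planted_indirect, ]
      # the module regulates the direct TFs: part of each planted direct
      # TF's activity is driven by the shared factor
      dir_u <- union(names(planted_direct_a), names(planted_direct_b))
      act[dir_u, ] <-
        sqrt(indirect_drive) * rep(common, each = length(dir_u)) +
        sqrt(1 - indirect_drive) * act[dir_u, ]
    }

    # network: TF -> own targets
    tgt_names <- as.vector(vapply(tfs, function(t)
      sprintf("%s_G%02d", t, seq_len(n_targets_per_tf)),
      character(n_targets_per_tf)))
    edges <- tibble::tibble(
      regulator = rep(tfs, each = n_targets_per_tf),
      target = tgt_names,
      source = "synthetic",
      weight = stats::runif(length(tgt_names), 0.5, 1.5)
    )
    # every TF is a candidate direct regulator (edge onto the target gene);
    # only planted TFs contribute to its expression
    direct_union <- union(names(planted_direct_a), names(planted_direct_b))
    es_tg <- stats::setNames(stats::runif(n_tfs, 0.8, 1.2), tfs)
    edges <- dplyr::bind_rows(edges, tibble::tibble(
      regulator = tfs, target = target_gene, source = "synthetic",
      weight = unname(es_tg)
    ))
    # planted indirect TFs -> coding genes of planted direct TFs, and
    # cross-regulation within the module (so the module is densely
    # connected in the network, not just correlated in activity)
    if (length(planted_indirect)) {
      edges <- dplyr::bind_rows(edges, tibble::tibble(
        regulator = rep(planted_indirect, times = length(direct_union)),
        target = rep(direct_union, each = length(planted_indirect)),
        source = "synthetic", weight = 1
      ))
      if (length(planted_indirect) >= 2L) {
        prs <- utils::combn(planted_indirect, 2L)
        edges <- dplyr::bind_rows(edges, tibble::tibble(
          regulator = prs[1L, ], target = prs[2L, ],
          source = "synthetic", weight = 1
        ))
      }
    }
    # sparse random background TF -> TF edges
    others <- setdiff(tfs, c(direct_union, planted_indirect))
    if (length(others) >= 2L) {
      n_bg <- min(length(others), n_tfs)
      from <- sample(others, n_bg, replace = TRUE)
      to <- sample(tfs, n_bg, replace = TRUE)
      ok <- from != to
      if (any(ok)) {
        edges <- dplyr::bind_rows(edges, tibble::tibble(
          regulator = from[ok], target = to[ok], source = "synthetic",
          weight = stats::runif(sum(ok), 0.2, 0.8)
        ))
      }
    }
    edges <- dplyr::distinct(edges, .data$regulator, .data$target,
                             .keep_all = TRUE)

    # expression: TF target genes track the TF's latent activity
    expr <- matrix(NA_real_, nrow = 0, ncol = n)
    tg_rows <- act[rep(seq_len(n_tfs), each = n_targets_per_tf), ,
                   drop = FALSE] +
      matrix(stats::rnorm(length(tgt_names) * n, sd = target_noise_sd),
             nrow = length(tgt_names))
    rownames(tg_rows) <- tgt_names

    # TF coding genes: noise, plus module signal on planted direct genes
    tf_rows <- matrix(stats::rnorm(n_tfs * n), nrow = n_tfs,
                      dimnames = list(tfs, samples))
    if (length(planted_indirect)) {
      drive <- colMeans(act[planted_indirect, , drop = FALSE])
      for (d in direct_union) {
        tf_rows[d, ] <- drive + stats::rnorm(n, sd = target_noise_sd)
      }
    }

    # target gene per condition from that condition's planted model
    tg <- beta0 + stats::rnorm(n, sd = noise_sd)
    for (t in names(planted_direct_a)) {
      ia <- condition == "A"
      tg[ia] <- tg[ia] + planted_direct_a[[t]] * es_tg[[t]] * act[t, ia]
    }
    for (t in names(planted_direct_b)) {
      ib <- condition == "B"
      tg[ib] <- tg[ib] + planted_direct_b[[t]] * es_tg[[t]] * act[t, ib]
    }

    values <- rbind(matrix(tg, nrow = 1,
                           dimnames = list(target_gene, samples)),
                    tf_rows, tg_rows)
    if (na_frac > 0) {
      mask <- stats::runif(length(values)) < na_frac
      values[mask] <- NA_real_
    }
  })

  truth <- list(
    planted_direct_a = planted_direct_a,
    planted_direct_b = planted_direct_b,
    planted_indirect = planted_indirect,
    es_target = es_tg, beta0 = beta0,
    module_correlation = module_correlation, indirect_drive = indirect_drive,
    noise_sd = noise_sd,
    target_noise_sd = target_noise_sd, na_frac = na_frac,
    n_samples = c(A = n_samples_a, B = n_samples_b),
    target_gene = target_gene, seed = seed
  )
  list(
    expression = new_expr_matrix(values, condition = condition),
    network = regulatory_network(edges),
    truth = truth
  )
}

#' Write a simulated dataset to a directory
#'
#' Emits the package's TSV formats (expression, condition labels, network)
#' plus the planted truth as JSON, so a simulation can be re-consumed through
#' the file-reading entry points.
#'
#' @param sim Result of [simulate_regulation()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(sim$expression, file.path(dir, "expression.tsv"))
  utils::write.table(
    data.frame(sample_id = names(sim$expression$condition),
               condition = unname(sim$expression$condition)),
    file.path(dir, "conditions.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  write_network(sim$network, file.path(dir, "network.tsv"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
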