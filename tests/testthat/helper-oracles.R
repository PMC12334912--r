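# Independent exhaustive motif scan used to vouch for the enumerators.
# Deliberately written as a plain triple/pair loop over node symbols with
# an edge lookup table -- no shared code with the package's join-based
# implementation.

oracle_edge_env <- function(net) {
  env <- new.env(parent = emptyenv())
  e <- net$edges
  for (i in seq_len(nrow(e))) {
    key <- paste(e$source[i], e$target[i])
    cur <- if (exists(key, envir = env)) get(key, envir = env) else list()
    cur[[length(cur) + 1]] <- list(sign = e$sign[i], mech = e$mechanism[i])
    assign(key, cur, envir = env)
  }
  env
}

oracle_lookup <- function(env, a, b) {
  key <- paste(a, b)
  if (exists(key, envir = env)) get(key, envir = env) else NULL
}

# Returns sorted string sets for FFLs and canonical-rotation FBL2/FBL3s.
oracle_motifs <- function(net) {
  syms <- sort(net$nodes$symbol)
  env <- oracle_edge_env(net)
  ffl <- character(); fbl3 <- character(); fbl2 <- character()
  for (A in syms) {
    for (B in syms) {
      if (B == A) next
      eAB <- oracle_lookup(env, A, B)
      eBA <- oracle_lookup(env, B, A)
      if (!is.null(eAB) && !is.null(eBA) && A < B) {
        for (x in eAB) for (y in eBA) {
          fbl2 <- c(fbl2, paste("FBL2", A, B, NA, x$sign, y$sign, NA,
                                x$mech, y$mech, NA))
        }
      }
      if (is.null(eAB)) next
      for (C in syms) {
        if (C == A || C == B) next
        eBC <- oracle_lookup(env, B, C)
        if (is.null(eBC)) next
        eAC <- oracle_lookup(env, A, C)
        if (!is.null(eAC)) {
          for (x in eAB) for (y in eBC) for (z in eAC)
            ffl <- c(ffl, paste("FFL", A, B, C, x$sign, y$sign, z$sign,
                                x$mech, y$mech, z$mech))
        }
        eCA <- oracle_lookup(env, C, A)
        if (!is.null(eCA) && A < B && A < C) {
          for (x in eAB) for (y in eBC) for (z in eCA)
            fbl3 <- c(fbl3, paste("FBL3", A, B, C, x$sign, y$sign, z$sign,
                                  x$mech, y$mech, z$mech))
        }
      }
    }
  }
  list(ffl = sort(ffl), fbl2 = sort(fbl2), fbl3 = sort(fbl3))
}

within_signs_flipped <- function(tbl) {
  tbl$s1 <- -tbl$s1
  tbl$s2 <- -tbl$s2
  tbl$s3 <- -tbl$s3
  tbl
}

motif_strings <- function(tbl) {
  if (!nrow(tbl)) return(character())
  sort(paste(tbl$kind, tbl$m1, tbl$m2, tbl$m3, tbl$s1, tbl$s2, tbl$s3,
             tbl$mech1, tbl$mech2, tbl$mech3))
}

# dense-grid sign-change count of SOX10 fixed points in the feedback loop,
# from the 1-D reduced steady-state equation written out independently
oracle_fbl_root_count <- function(p, atf2, s_max = NULL, n_grid = 4000) {
  if (is.null(s_max)) s_max <- p$beta_s / p$delta_s * 1.02
  g <- function(S) {
    m <- p$beta_mir * S^p$n_sm / (p$k_sm^p$n_sm + S^p$n_sm) / p$delta_mir
    A <- max(atf2 + p$atf2_basal, 0) * p$k_ma^p$n_ma /
      (p$k_ma^p$n_ma + m^p$n_ma)
    p$beta_s * p$k_as^p$n_as / (p$k_as^p$n_as + A^p$n_as) / p$delta_s - S
  }
  Sg <- seq(0, s_max, length.out = n_grid)
  v <- vapply(Sg, g, 0)
  sum(v[-1] * v[-length(v)] < 0)
}

random_test_network <- function(seed, max_nodes = 50) {
  withr::with_seed(seed, {
    n_tf <- sample(2:10, 1)
    n_mir <- sample(1:6, 1)
    n_pcg <- sample(2:(max_nodes - n_tf - n_mir), 1)
    p <- runif(1, 0.03, 0.15)
  })
  generate_random_network(n_tf, n_mir, n_pcg, edge_prob = p,
                          p_activation = 0.6, seed = seed + 1000L)
}
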