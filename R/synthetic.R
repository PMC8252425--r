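#' Build a generator configuration
#'
#' Loads a preset (`"cba1"` or `"cba2"`, shipped as YAML under
#' `inst/extdata/`) and applies overrides. The preset values transcribe the
#' study conditions: per-row Y-shape geometry means/SDs, the 4/3/2 mosaic span
#' rule, type-2 fiber trajectory and innervation parameters, and the MOC
#' mixture. Overrides are named nested lists merged over the preset.
#'
#' @param preset `"cba1"` (default) or `"cba2"`, or a path to a YAML file.
#' @param overrides nested named list merged over the preset.
#' @return validated list of class `oc_config`.
#' @export
oc_config <- function(preset = "cba1", overrides = list()) {
  path <- if (file.exists(preset)) preset else
    system.file("extdata", paste0(preset, ".yaml"), package = "cortimorph")
  if (!nzchar(path) || !file.exists(path)) {
    abort(sprintf("unknown preset '%s'", preset), class = "cortimorph_bad_input")
  }
  cfg <- yaml::read_yaml(path)
  cfg <- modify_list_deep(cfg, overrides)
  validate_config(cfg)
  structure(cfg, class = "oc_config")
}

#' @keywords internal
modify_list_deep <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modify_list_deep(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' @keywords internal
validate_config <- function(cfg) {
  y <- cfg$yshape
  for (f in c("L_OHC", "L_PhP", "L_DC", "alpha", "beta_DC", "beta_OHC")) {
    if (any(y[[f]]$sd < 0)) abort(sprintf("%s: sd must be >= 0", f))
    if (any(unlist(y[[f]]$mean) <= 0)) abort(sprintf("%s: mean must be > 0", f))
  }
  probs <- c(cfg$t2sgn$mixing_prob, cfg$moc$branched_fraction,
             cfg$t2sgn$ribbon_fraction, cfg$moc$unbranched_row_probs,
             cfg$moc$branched_row_probs)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  for (f in c("unbranched_row_probs", "branched_row_probs")) {
    if (abs(sum(cfg$moc[[f]]) - 1) > 1e-6) {
      abort(sprintf("moc$%s must sum to 1", f))
    }
  }
  if (sum(cfg$t2sgn$row_split) != cfg$t2sgn$n_fibers) {
    abort("t2sgn$row_split must sum to n_fibers")
  }
  invisible(cfg)
}

## ---------------------------------------------------------------------------
## low-level skeleton assembly

#' @keywords internal
new_tree_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$xyz <- list()
  env$edges <- list()
  env$n <- 0L
  env
}

#' @keywords internal
tb_add_chain <- function(tb, xyz, attach_to = NA_integer_) {
  k <- nrow(xyz)
  ids <- tb$n + seq_len(k)
  tb$xyz[[length(tb$xyz) + 1]] <- xyz
  tb$n <- tb$n + k
  e_from <- c(if (!is.na(attach_to)) attach_to else integer(), ids[-k])
  e_to <- c(if (!is.na(attach_to)) ids[1] else integer(),
            if (k > 1) ids[-1] else integer())
  if (length(e_from) > 0) {
    tb$edges[[length(tb$edges) + 1]] <- cbind(e_from, e_to)
  }
  ids
}

#' @keywords internal
tb_finish <- function(tb, tree_id, cell_class, row, landmarks, pitch) {
  xyz <- do.call(rbind, tb$xyz)
  dimnames(xyz) <- NULL
  # snap to the voxel grid (annotation coordinates are integer voxels)
  xyz[, 1] <- round(xyz[, 1] / pitch[["dx"]]) * pitch[["dx"]]
  xyz[, 2] <- round(xyz[, 2] / pitch[["dy"]]) * pitch[["dy"]]
  xyz[, 3] <- round(xyz[, 3] / pitch[["dz"]]) * pitch[["dz"]]
  nodes <- tibble(node_id = seq_len(tb$n), x = xyz[, 1], y = xyz[, 2],
                  z = xyz[, 3], radius = NA_real_)
  ed <- if (length(tb$edges) > 0) do.call(rbind, tb$edges) else
    cbind(integer(), integer())
  skeleton_tree(tree_id, cell_class, row, nodes,
                tibble(from = as.integer(ed[, 1]), to = as.integer(ed[, 2])),
                landmarks)
}

#' Sample node positions along a straight segment with smooth bow jitter
#'
#' Endpoints are exact; interior nodes get a low-frequency quadratic bow
#' (amplitude `bow_sd` nm per perpendicular axis, emulating gentle
#' cytoskeletal curvature) plus small node-level tracing noise. The bow is
#' symmetric, so arc-length inflation and principal-axis rotation are
#' negligible at the default amplitudes.
#'
#' @keywords internal
segment_nodes <- function(from, to, spacing_nm, bow_sd = 0, node_sd = 0,
                          drop_first = FALSE) {
  d <- to - from
  len <- sqrt(sum(d^2))
  k <- max(2, ceiling(len / spacing_nm) + 1)
  t <- seq(0, 1, length.out = k)
  pts <- outer(rep(1, k), from) + outer(t, d)
  if (bow_sd > 0 || node_sd > 0) {
    ax <- d / len
    ref <- if (abs(ax[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- pracma_cross(ax, ref); e1 <- e1 / sqrt(sum(e1^2))
    e2 <- pracma_cross(ax, e1)
    interior <- seq_len(k) > 1 & seq_len(k) < k
    bow <- 4 * t * (1 - t)
    a1 <- rnorm(1, 0, bow_sd); a2 <- rnorm(1, 0, bow_sd)
    pts <- pts + outer(bow * interior, a1 * e1 + a2 * e2)
    if (node_sd > 0) {
      pts[interior, ] <- pts[interior, ] +
        matrix(rnorm(3 * sum(interior), 0, node_sd), ncol = 3)
    }
  }
  if (drop_first) pts[-1, , drop = FALSE] else pts
}

## ---------------------------------------------------------------------------
## lattice (OHC / DC / OPC) generation

#' Solve the PhP direction on the alpha-cone with a fixed longitudinal run
#'
#' Finds the unit vector `v` with `u . v = cos(alpha)` and `v[1] = vx_req`
#' (positive radial component). When `vx_req` lies outside the cone's
#' longitudinal reach, `v` is clipped to the cone boundary (alpha is always
#' preserved; the longitudinal run then falls short) and `clipped = TRUE`.
#'
#' @keywords internal
solve_php_direction <- function(u, alpha_deg, vx_req) {
  ca <- cos(deg2rad(alpha_deg))
  sa <- sin(deg2rad(alpha_deg))
  ux <- u[1]; uz <- u[3]
  vx_max <- ux * ca + sqrt(max(0, 1 - ux^2)) * sa
  vx_min <- ux * ca - sqrt(max(0, 1 - ux^2)) * sa
  clipped <- FALSE
  vx <- vx_req
  if (vx > vx_max) { vx <- vx_max; clipped <- TRUE }
  if (vx < vx_min) { vx <- vx_min; clipped <- TRUE }
  vz <- (ca - ux * vx) / uz
  vy2 <- 1 - vx^2 - vz^2
  vy <- sqrt(max(0, vy2))
  list(v = c(vx, vy, vz), clipped = clipped)
}

#' Generate the OHC/DC/OPC lattice
#'
#' Columns sit on a longitudinal grid; the reticular-lamina mosaic of OHC
#' apices is regular (the biological constraint), so the DC roots absorb the
#' per-complex geometry variation. Per-complex lengths and angles are drawn
#' from the preset truncated Gaussians and realized exactly by construction;
#' each PhP inserts at the RL column `span - 1` columns basal of its own OHC
#' apex. Basal-edge DCs whose PhP insertion would leave the lattice lose their
#' insertion landmark (the intact-complex census).
#'
#' @param config an [oc_config()].
#' @return list `trees` (list of [skeleton_tree()]), `ledger_complexes`,
#'   `ledger_opcs`, `apex_grid` (internal), plus frame truth.
#' @keywords internal
generate_lattice <- function(config) {
  lat <- config$lattice
  y <- config$yshape
  p <- lat$column_pitch_um * NM_PER_UM
  rowsp <- lat$row_spacing_um * NM_PER_UM
  nC <- lat$n_columns
  spacing <- lat$node_spacing_um * NM_PER_UM
  trees <- list()
  ledger <- list()
  # mean apex offset per row (apex x relative to column grid)
  d_mean <- map_dbl(1:3, function(r) {
    (y$L_DC$mean[r] * cos(deg2rad(y$beta_DC$mean[r])) +
       y$L_OHC$mean[r] * cos(deg2rad(y$beta_OHC$mean[r]))) * NM_PER_UM
  })
  col_x <- function(j, r) {
    (j - 1) * p + (if (r == 2) lat$row2_stagger * p else 0)
  }
  span_rule <- y$span_rule
  dropout <- lat$dropout_basal
  apex_x_tab <- matrix(NA_real_, nrow = 3, ncol = nC)
  for (r in 1:3) {
    for (j in 1:nC) {
      apex_x_tab[r, j] <- col_x(j, r) + d_mean[r] + rnorm(1, 0, lat$apex_x_sd_nm)
    }
  }
  for (r in 1:3) {
    for (j in 1:nC) {
      ok <- FALSE
      for (try in 1:25) {
        L_ohc <- rtruncnorm(1, y$L_OHC$mean[r], y$L_OHC$sd[r]) * NM_PER_UM
        L_php <- rtruncnorm(1, y$L_PhP$mean[r], y$L_PhP$sd[r]) * NM_PER_UM
        L_dc <- rtruncnorm(1, y$L_DC$mean[r], y$L_DC$sd[r]) * NM_PER_UM
        alpha <- rtruncnorm(1, y$alpha$mean[r], y$alpha$sd[r])
        b_dc <- rtruncnorm(1, y$beta_DC$mean[r], y$beta_DC$sd[r])
        b_ohc <- rtruncnorm(1, y$beta_OHC$mean[r], y$beta_OHC$sd[r])
        u_dc <- c(cos(deg2rad(b_dc)), 0, sin(deg2rad(b_dc)))
        u_ohc <- c(cos(deg2rad(b_ohc)), 0, sin(deg2rad(b_ohc)))
        apex <- c(apex_x_tab[r, j],
                  (r - 1) * rowsp + rnorm(1, 0, lat$root_xy_sd_nm),
                  rnorm(1, 0, lat$root_z_sd_nm) +
                    (y$L_DC$mean[r] * sin(deg2rad(y$beta_DC$mean[r])) +
                       y$L_OHC$mean[r] * sin(deg2rad(y$beta_OHC$mean[r]))) * NM_PER_UM)
        base <- apex - L_ohc * u_ohc          # OHC basal pole = DC cup
        root <- base - L_dc * u_dc            # DC root on the BM
        # pull the root onto the BM plane (z ~ 0): shift the whole complex
        dz <- root[3] - rnorm(1, 0, lat$root_z_sd_nm)
        root[3] <- root[3] - dz; base[3] <- base[3] - dz; apex[3] <- apex[3] - dz
        span_target <- span_rule[r]
        ins_col <- j + span_target - 1
        has_insertion <- ins_col <= nC
        ins_x <- if (has_insertion) apex_x_tab[r, ins_col] else
          col_x(ins_col, r) + d_mean[r]
        vx_req <- (ins_x - base[1]) / L_php
        sol <- solve_php_direction(u_ohc, alpha, vx_req)
        insertion <- base + L_php * sol$v
        miss <- abs(insertion[1] - ins_x)
        if (sol$v[3] > 0.1 && miss < 0.45 * p) { ok <- TRUE; break }
      }
      if (!ok) {
        # keep the last draw; flag it (extremely rare under the presets)
        warn(sprintf("complex row %d col %d: span construction clipped", r, j))
      }
      ohc_id <- sprintf("OHC%d_%03d", r, j)
      dc_id <- sprintf("DC%d_%03d", r, j)
      # a complex is incomplete when configured as edge dropout or when its
      # PhP insertion column lies beyond the annotated volume
      dropped <- j > nC - dropout[r] || !has_insertion
      # OHC tree
      tb <- new_tree_builder()
      ids <- tb_add_chain(tb, segment_nodes(base, apex, spacing,
                                            lat$bow_sd_nm, lat$node_sd_nm))
      lms <- c(basal_pole = ids[1], cuticular_plate = ids[length(ids)])
      trees[[ohc_id]] <- tb_finish(tb, ohc_id, "OHC", r, lms, config$pitch_nm)
      # DC tree: trunk root->cup, then PhP cup->insertion
      tb <- new_tree_builder()
      trunk <- tb_add_chain(tb, segment_nodes(root, base, spacing,
                                              lat$bow_sd_nm, lat$node_sd_nm))
      php <- tb_add_chain(tb, segment_nodes(base, insertion, spacing,
                                            lat$bow_sd_nm, lat$node_sd_nm,
                                            drop_first = TRUE),
                          attach_to = trunk[length(trunk)])
      lms <- c(DC_root = trunk[1], PhP_branch_point = trunk[length(trunk)])
      if (!dropped) {
        lms <- c(lms, PhP_apical_insertion = php[length(php)])
      }
      trees[[dc_id]] <- tb_finish(tb, dc_id, "DC", r, lms, config$pitch_nm)
      ledger[[length(ledger) + 1]] <- tibble(
        complex_id = dc_id, ohc_id = ohc_id, row = r, column = j,
        L_OHC = L_ohc / NM_PER_UM, L_PhP = L_php / NM_PER_UM,
        L_DC = L_dc / NM_PER_UM,
        alpha = alpha, beta_DC = b_dc, beta_OHC = b_ohc,
        beta_PhP = rad2deg(acos(sol$v[1])),
        span_target = as.integer(span_target),
        clipped = sol$clipped, dropped = dropped,
        root_x = root[1], root_y = root[2], root_z = root[3],
        base_x = base[1], base_y = base[2], base_z = base[3],
        apex_x = apex[1], apex_y = apex[2], apex_z = apex[3])
    }
  }
  # OPC row
  opc_ledger <- list()
  for (j in 1:nC) {
    b_opc <- rtruncnorm(1, y$beta_OPC$mean, y$beta_OPC$sd)
    L_opc <- rtruncnorm(1, y$L_OPC$mean, y$L_OPC$sd) * NM_PER_UM
    base <- c(col_x(j, 1) + rnorm(1, 0, lat$root_xy_sd_nm),
              -lat$opc_offset_um * NM_PER_UM + rnorm(1, 0, lat$root_xy_sd_nm),
              rnorm(1, 0, lat$root_z_sd_nm))
    apex <- base + L_opc * c(cos(deg2rad(b_opc)), 0, sin(deg2rad(b_opc)))
    opc_id <- sprintf("OPC1_%03d", j)
    tb <- new_tree_builder()
    ids <- tb_add_chain(tb, segment_nodes(base, apex, spacing,
                                          lat$bow_sd_nm, lat$node_sd_nm))
    trees[[opc_id]] <- tb_finish(tb, opc_id, "OPC", 1L,
                                 c(OPC_base = ids[1], OPC_apex = ids[length(ids)]),
                                 config$pitch_nm)
    opc_ledger[[j]] <- tibble(opc_id = opc_id, column = j,
                              beta_OPC = b_opc, L_OPC = L_opc / NM_PER_UM,
                              base_x = base[1], base_y = base[2], base_z = base[3])
  }
  list(trees = trees,
       ledger_complexes = bind_rows(ledger),
       ledger_opcs = bind_rows(opc_ledger),
       bm_normal = c(0, 0, 1), basal_hint = c(1, 0, 0),
       row_direction = c(1, 0, 0))
}

## ---------------------------------------------------------------------------
## type-2 SGN generation

#' @keywords internal
trunk_point_at_height <- function(root, u_dc, z_nm) {
  # point on a DC trunk (root + t*u) at height z
  t <- (z_nm - root[3]) / u_dc[3]
  root + t * u_dc
}

#' Column-wise fiber lane scheduler
#'
#' Assigns each in-lattice fiber a supporting-cell row lane per column so that
#' per-column attachment quotas (row 1 first, then rows 2-3 with the leftover
#' fiber supply) are met, with lane persistence and adjacent-row moves
#' preferred.
#'
#' @keywords internal
schedule_lanes <- function(n_fibers, n_cols, present, quotas, elig) {
  lane <- matrix(NA_integer_, nrow = n_fibers, ncol = n_cols)
  cur <- rep(NA_integer_, n_fibers)
  for (j in seq_len(n_cols)) {
    avail <- which(present[, j])
    if (length(avail) == 0) next
    q <- quotas[[j]]
    if (is.null(q)) {
      # edge column: persist current lanes when still eligible
      keepable <- avail[!is.na(cur[avail]) & elig[cbind(avail, j, pmax(1, cur[avail]))]]
      lane[keepable, j] <- cur[keepable]
      next
    }
    assigned <- rep(NA_integer_, n_fibers)
    remaining <- avail
    # row 1 is filled first (its abundance is the tightest contract); rows
    # 2-3 follow most-height-constrained first so short trunks still fill
    slack <- vapply(2:3, function(r) sum(elig[avail, j, r]) - q[r], numeric(1))
    for (r in c(1L, (2:3)[order(slack)])) {
      cand <- remaining[elig[remaining, j, r]]
      want <- min(q[r], length(cand))
      if (want == 0) next
      # prefer fibers already on this lane, then adjacent lanes, then gap
      score <- abs(cur[cand] - r)
      score[is.na(score)] <- 1.5
      pick <- cand[order(score, cand)][seq_len(want)]
      assigned[pick] <- r
      remaining <- setdiff(remaining, pick)
    }
    lane[avail, j] <- assigned[avail]
    cur[avail] <- ifelse(is.na(assigned[avail]), cur[avail], assigned[avail])
  }
  lane
}

#' Generate the type-2 spiral ganglion fiber population
#'
#' Each fiber enters radially, turns ~90 degrees at the outer-pillar row and
#' runs basally with an exactly biphasic height profile: the sampled climbing
#' slope up to its first OHC-innervating collateral, the sampled contact slope
#' after. Lane scheduling along the DC rows realizes the configured per-DC
#' attachment abundances (row 1 exactly; rows 2-3 limited by the 40-fiber
#' supply). Collateral contacts are drawn per OHC from the configured per-row
#' count distributions; bouton classes follow the per-row ribbon fractions;
#' each fiber samples one OHC row unless selected as a row-mixing fiber.
#'
#' @keywords internal
generate_t2sgn <- function(config, lattice) {
  t2 <- config$t2sgn
  lat <- config$lattice
  p <- lat$column_pitch_um * NM_PER_UM
  nC <- lat$n_columns
  nF <- t2$n_fibers
  lx <- lattice$ledger_complexes
  lx_key <- matrix(NA_integer_, 3, nC)
  lx_key[cbind(lx$row, lx$column)] <- seq_len(nrow(lx))
  lx_root <- cbind(lx$root_x, lx$root_y, lx$root_z)
  lx_base <- cbind(lx$base_x, lx$base_y, lx$base_z)
  lx_beta <- lx$beta_DC
  lx_ohc <- lx$ohc_id
  # per-fiber draws -----------------------------------------------------------
  target_row <- sample(rep(1:3, times = t2$row_split))
  # fixed-count realization (like the MOC subtype split): the census fraction
  # of row-mixing fibers equals the configured probability by construction,
  # the seeded draw decides which fibers mix
  mixing <- rep(FALSE, nF)
  n_mix <- round(t2$mixing_prob * nF)
  if (n_mix > 0) mixing[sample(nF, n_mix)] <- TRUE
  secondary <- ifelse(target_row == 1, 2L,
                      ifelse(target_row == 3, 2L,
                             ifelse(runif(nF) < 0.5, 1L, 3L)))
  secondary[!mixing] <- NA_integer_
  s_climb <- rtruncnorm(nF, t2$climbing_slope$mean, t2$climbing_slope$sd)
  s_contact <- rtruncnorm(nF, t2$contact_slope$mean, t2$contact_slope$sd)
  h0 <- rtruncnorm(nF, t2$turn_height_um$mean, t2$turn_height_um$sd)
  h_bp <- rtruncnorm(nF, t2$contact_height_um$mean, t2$contact_height_um$sd)
  # planned breakpoint columns, staggered per target row so every OHC column
  # has candidate fibers; fibers with the steepest contact slopes take the
  # basal-most breakpoints so their riding band stays anchored (the height
  # correction below scales with the breakpoint-to-census distance)
  bp_col <- integer(nF)
  for (r in 1:3) {
    idx <- which(target_row == r)
    cols_r <- round(seq(t2$breakpoint_columns[1], t2$breakpoint_columns[2],
                        length.out = length(idx)))
    bp_col[idx[order(abs(s_contact[idx]))]] <- cols_r
  }
  x_bp_plan <- (bp_col - 1) * p
  # anchor each contact compartment on the target riding band at the census
  # zone midpoint: the breakpoint height is offset so the fiber passes the
  # census columns at the configured contact height regardless of its
  # contact-slope draw (keeps the riding band within trunk reach there)
  x_cmid <- mean((seq(t2$census_columns[1], t2$census_columns[2]) - 1) * p)
  h_bp <- h_bp - s_contact * (x_cmid - x_bp_plan) / NM_PER_UM
  run <- (h_bp - h0) / s_climb
  run <- pmin(pmax(run, t2$climb_run_um$min), t2$climb_run_um$max)
  x_turn <- x_bp_plan - run * NM_PER_UM
  y_turn <- -lat$opc_offset_um * NM_PER_UM + rnorm(nF, 0, 1000)
  # contact assignment --------------------------------------------------------
  ohc_mu <- t2$ohc_contacts$mean
  ohc_sd <- t2$ohc_contacts$sd
  contacts_plan <- list()  # per fiber: integer vector of columns
  for (i in seq_len(nF)) contacts_plan[[i]] <- integer()
  contact_rows <- list()
  for (i in seq_len(nF)) contact_rows[[i]] <- integer()
  for (r in 1:3) {
    cand_primary <- which(target_row == r)
    cand_secondary <- which(mixing & secondary == r)
    for (j in 1:nC) {
      cand <- c(cand_primary, cand_secondary)
      cand <- cand[bp_col[cand] <= j]
      if (length(cand) == 0) next
      k <- stochastic_round(pmax(0, rtruncnorm(1, ohc_mu[r], ohc_sd[r])))
      if (k == 0) next
      pick <- cand[sample.int(length(cand), k, replace = TRUE)]
      for (f in pick) {
        contacts_plan[[f]] <- c(contacts_plan[[f]], j)
        contact_rows[[f]] <- c(contact_rows[[f]], r)
      }
    }
  }
  # every fiber needs >= 1 contact; mixing fibers need both rows
  for (i in seq_len(nF)) {
    if (length(contacts_plan[[i]]) == 0) {
      jj <- min(nC, bp_col[i] + sample(0:3, 1))
      contacts_plan[[i]] <- jj
      contact_rows[[i]] <- target_row[i]
    }
    if (mixing[i]) {
      rows_have <- unique(contact_rows[[i]])
      for (need in c(target_row[i], secondary[i])) {
        if (!need %in% rows_have) {
          # convert the last contact to the missing row at the same column
          k <- length(contact_rows[[i]])
          if (k >= 2) contact_rows[[i]][k] <- need else {
            contacts_plan[[i]] <- c(contacts_plan[[i]],
                                    min(nC, contacts_plan[[i]][1] + 1))
            contact_rows[[i]] <- c(contact_rows[[i]], need)
          }
        }
      }
    }
  }
  first_col <- map_int(seq_len(nF), ~ min(contacts_plan[[.x]]))
  # lane scheduling ------------------------------------------------------------
  col_x_centers <- (seq_len(nC) - 1) * p
  present <- vapply(seq_len(nC), function(j) {
    col_x_centers[j] > x_turn & col_x_centers[j] <= (nC - 1) * p + 1
  }, logical(nF))
  quotas <- map(seq_len(nC), function(j) {
    if (j >= t2$quota_columns[1] && j <= t2$quota_columns[2]) {
      c(max(0, round(rtruncnorm(1, t2$dc_abundance$mean[1], t2$dc_abundance$sd[1]))),
        max(0, round(rtruncnorm(1, t2$dc_abundance$mean[2], t2$dc_abundance$sd[2]))),
        max(0, round(rtruncnorm(1, t2$dc_abundance$mean[3], t2$dc_abundance$sd[3]))))
    } else NULL
  })
  # height eligibility: a fiber can only ride a trunk whose top it can reach
  x_bp_act <- (first_col - 1) * p
  z_prov <- vapply(seq_len(nC), function(j) {
    x <- col_x_centers[j]
    ifelse(x <= x_bp_act,
           h0 * NM_PER_UM + s_climb * (x - x_turn),
           h0 * NM_PER_UM + s_climb * (x_bp_act - x_turn) +
             s_contact * (x - x_bp_act))
  }, numeric(nF))
  elig <- array(FALSE, dim = c(nF, nC, 3))
  for (r in 1:3) {
    top <- lx_base[lx_key[r, ], 3]  # trunk-top height per column
    elig[, , r] <- present &
      (z_prov <= matrix(top + 700, nF, nC, byrow = TRUE)) &
      (z_prov >= 2000)
  }
  lanes <- schedule_lanes(nF, nC, present, quotas, elig)
  # geometry -------------------------------------------------------------------
  trees <- list()
  contact_records <- list()
  fiber_ledger <- list()
  attach_ledger <- list()
  spacing <- t2$node_spacing_um * NM_PER_UM
  for (i in seq_len(nF)) {
    fid <- sprintf("T2SGN_%03d", i)
    height_fn_factory <- function(x_bp_nm, h0_i, sc, sct, xt) {
      z_bp <- (h0_i + sc * (x_bp_nm - xt) / NM_PER_UM) * NM_PER_UM
      function(x) {
        ifelse(x <= x_bp_nm,
               (h0_i * NM_PER_UM + sc * (x - xt)),
               z_bp + sct * (x - x_bp_nm))
      }
    }
    # waypoints along the post-turn run
    cols_i <- which(!is.na(lanes[i, ]) | seq_len(nC) %in% contacts_plan[[i]])
    cols_i <- sort(unique(c(cols_i, first_col[i])))
    cols_i <- cols_i[col_x_centers[cols_i] > x_turn[i]]
    # waypoint (x, y) for one column: on the scheduled lane's trunk at the
    # fiber's height there, or in the gap lane; returns the attachment row
    # actually realized (NA when out of trunk reach)
    waypoint_xy <- function(j, zj, hf) {
      r_lane <- lanes[i, j]
      if (!is.na(r_lane)) {
        k <- lx_key[r_lane, j]
        root <- lx_root[k, ]
        u_dc <- c(cos(deg2rad(lx_beta[k])), 0, sin(deg2rad(lx_beta[k])))
        off <- rnorm(2, 0, t2$attach_offset_sd_um * NM_PER_UM / 2)
        off <- pmin(pmax(off, -1200), 1200)
        # one fixed-point pass: the node's height is a function of its x, so
        # re-evaluate the trunk point at the height the node will actually have
        z_use <- min(zj, lx_base[k, 3] - 500)
        for (it in 1:2) {
          q <- trunk_point_at_height(root, u_dc, z_use)
          z_node <- hf(q[1] + off[1])
          z_use <- min(z_node, lx_base[k, 3] - 500)
        }
        q <- trunk_point_at_height(root, u_dc, z_use)
        dz <- max(0, hf(q[1] + off[1]) - z_use)
        # when the fiber rides above a short trunk's top, shrink the radial
        # offset so the attachment stays well inside the analyzer radius
        if (dz > 0) {
          max_off <- sqrt(max(0, 1700^2 - min(dz, 1650)^2))
          onorm <- sqrt(sum(off^2))
          if (onorm > max_off) off <- off * max_off / max(onorm, 1)
        }
        dist <- sqrt(max(0, hf(q[1] + off[1]) - z_use)^2 + sum(off^2))
        list(xy = c(q[1] + off[1], q[2] + off[2]),
             row = if (dist <= 1750) r_lane else NA_integer_)
      } else {
        prev_lane <- lanes[i, seq_len(max(1, j - 1))]
        prev_lane <- prev_lane[!is.na(prev_lane)]
        base_row <- if (length(prev_lane) > 0) tail(prev_lane, 1) else 1L
        list(xy = c(col_x_centers[j],
                    (base_row - 1) * lat$row_spacing_um * NM_PER_UM + 3400 +
                      rnorm(1, 0, 300)),
             row = NA_integer_)
      }
    }
    # the kink of the biphasic profile sits exactly at the first-contact
    # waypoint, so both OLS compartments are exactly linear
    j0 <- first_col[i]
    hfun0 <- height_fn_factory(col_x_centers[j0], h0[i], s_climb[i],
                               s_contact[i], x_turn[i])
    wbp <- waypoint_xy(j0, hfun0(col_x_centers[j0]), hfun0)
    x_bp <- wbp$xy[1]
    hfun <- height_fn_factory(x_bp, h0[i], s_climb[i], s_contact[i], x_turn[i])
    cand <- map(cols_i, function(j) {
      if (j == j0) c(wbp$xy, wbp$row, j) else {
        res <- waypoint_xy(j, hfun(col_x_centers[j]), hfun)
        c(res$xy, res$row, j)
      }
    })
    cm <- do.call(rbind, cand)  # x, y, att_row, column
    # visit waypoints in x order (leaning trunks can swap column order);
    # drop near-coincident or pre-turn ones, never the breakpoint waypoint
    cm <- cm[order(cm[, 1]), , drop = FALSE]
    keep_wp <- rep(TRUE, nrow(cm))
    # the basal lead limb occupies the first ~7 um past the turn, so the
    # earliest lane waypoint sits clear of it
    last_x <- x_turn[i] + 9000
    for (w in seq_len(nrow(cm))) {
      if (cm[w, 1] <= last_x + 300 && !identical(cm[w, 4], as.numeric(j0))) {
        keep_wp[w] <- FALSE
      } else {
        last_x <- cm[w, 1]
      }
    }
    cm <- cm[keep_wp, , drop = FALSE]
    wp <- map(seq_len(nrow(cm)), ~ c(cm[.x, 1], cm[.x, 2], hfun(cm[.x, 1])))
    wp_att <- as.integer(cm[, 3])
    wp_col <- as.integer(cm[, 4])
    # short tail past the basal-most waypoint so a collateral at the last
    # column still leaves a fitted contact compartment
    x_tail <- wp[[length(wp)]][1] + 6000
    wp[[length(wp) + 1]] <- c(x_tail, wp[[length(wp)]][2], hfun(x_tail))
    wp_att <- c(wp_att, NA_integer_)
    wp_col <- c(wp_col, NA_integer_)
    # turn and inbound limb (radial approach with a slight basal-side tilt,
    # so the basal turn is the sharpest bend on the fiber)
    turn_pt <- c(x_turn[i], y_turn[i], h0[i] * NM_PER_UM)
    inbound_start <- turn_pt + c(9000, -22000, 0)
    tb <- new_tree_builder()
    inbound <- segment_nodes(inbound_start, turn_pt, spacing, 0, lat$node_sd_nm)
    ids_in <- tb_add_chain(tb, inbound)
    turn_node <- ids_in[length(ids_in)]
    prev_id <- turn_node
    prev_pt <- turn_pt
    # run straight basally for a few um before ramping onto the DC rows
    if (wp[[1]][1] > x_turn[i] + 7000) {
      x_lead <- x_turn[i] + 5000
      lead_pt <- c(x_lead, y_turn[i], hfun(x_lead))
      seg <- segment_nodes(prev_pt, lead_pt, spacing, 0, lat$node_sd_nm,
                           drop_first = TRUE)
      seg[, 3] <- hfun(seg[, 1])
      ids <- tb_add_chain(tb, seg, attach_to = prev_id)
      prev_id <- ids[length(ids)]
      prev_pt <- lead_pt
    }
    wp_node <- integer(length(wp))
    for (w in seq_along(wp)) {
      seg <- segment_nodes(prev_pt, wp[[w]], spacing, 0, lat$node_sd_nm,
                           drop_first = TRUE)
      # enforce the exact biphasic height on every sampled node
      seg[, 3] <- hfun(seg[, 1])
      ids <- tb_add_chain(tb, seg, attach_to = prev_id)
      wp_node[w] <- ids[length(ids)]
      prev_id <- wp_node[w]
      prev_pt <- wp[[w]]
    }
    trunk_end <- prev_id
    # collaterals + contact records
    cplan <- contacts_plan[[i]]
    crows <- contact_rows[[i]]
    for (ci in seq_along(cplan)) {
      j <- cplan[ci]; r <- crows[ci]
      w <- which(wp_col == j)[1]
      if (is.na(w)) next
      origin_id <- wp_node[w]
      origin_pt <- wp[[w]]
      k <- lx_key[r, j]
      bouton <- lx_base[k, ] + c(rnorm(2, 0, 200), -300)
      mid <- (origin_pt + bouton) / 2 + c(0, 0, 500)
      chain <- rbind(mid, bouton)
      tb_add_chain(tb, chain, attach_to = origin_id)
      cls <- if (runif(1) < t2$ribbon_fraction[r]) "afferent_ribbon" else
        "afferent_ribbonless"
      contact_records[[length(contact_records) + 1]] <- list(
        fiber_id = fid, target_id = lx_ohc[k], bouton_class = cls,
        x = bouton[1], y = bouton[2], z = bouton[3], node_id = origin_id)
    }
    lms <- c(entry = ids_in[1], trunk_end = trunk_end)
    trees[[fid]] <- tb_finish(tb, fid, "T2SGN", NA_integer_, lms, config$pitch_nm)
    fiber_ledger[[i]] <- tibble(
      fiber_id = fid, target_row = target_row[i], mixing = mixing[i],
      secondary_row = secondary[i],
      climbing_slope = s_climb[i], contact_slope = s_contact[i],
      h0_um = h0[i], x_turn_nm = x_turn[i], turn_node = turn_node,
      breakpoint_column = first_col[i],
      n_contacts = length(cplan))
    att <- which(!is.na(wp_att))
    if (length(att) > 0) {
      attach_ledger[[length(attach_ledger) + 1]] <- tibble(
        fiber_id = fid, column = wp_col[att], row = wp_att[att])
    }
  }
  contacts <- if (length(contact_records) > 0) bind_rows(contact_records) else
    empty_contacts()
  # snap contact positions to the voxel grid, matching the skeletons
  pt <- config$pitch_nm
  contacts$x <- round(contacts$x / pt$dx) * pt$dx
  contacts$y <- round(contacts$y / pt$dy) * pt$dy
  contacts$z <- round(contacts$z / pt$dz) * pt$dz
  list(trees = trees, contacts = contacts,
       ledger_fibers = bind_rows(fiber_ledger),
       ledger_attachments = bind_rows(attach_ledger),
       census_columns = seq(t2$census_columns[1], t2$census_columns[2]))
}

## ---------------------------------------------------------------------------
## MOC generation

#' Generate the medial olivocochlear fiber population
#'
#' Subtype counts are fixed (`round(branched_fraction * n_fibers)` branched;
#' which fibers is seeded), so a classifier fixture with an exact branched
#' fraction falls out of every run. Branched fibers bifurcate before the
#' tunnel slab (2-3 crossings); unbranched fibers cross once. Synapse counts
#' are drawn from the location-calibrated discrete Gaussians truncated to the
#' printed ranges; branched fibers concentrate synapses in a modal row.
#'
#' @keywords internal
generate_moc <- function(config, lattice) {
  mc <- config$moc
  lat <- config$lattice
  p <- lat$column_pitch_um * NM_PER_UM
  nC <- lat$n_columns
  nF <- mc$n_fibers
  lx <- lattice$ledger_complexes
  lx_key <- matrix(NA_integer_, 3, nC)
  lx_key[cbind(lx$row, lx$column)] <- seq_len(nrow(lx))
  lx_base <- cbind(lx$base_x, lx$base_y, lx$base_z)
  lx_ohc <- lx$ohc_id
  n_branched <- round(mc$branched_fraction * nF)
  is_branched <- rep(FALSE, nF)
  is_branched[sample(nF, n_branched)] <- TRUE
  tab_b <- calibrate_discrete_gaussian(mc$branched_synapses$mean,
                                       mc$branched_synapses$sd,
                                       mc$branched_synapses$min,
                                       mc$branched_synapses$max)
  tab_u <- calibrate_discrete_gaussian(mc$unbranched_synapses$mean,
                                       mc$unbranched_synapses$sd,
                                       mc$unbranched_synapses$min,
                                       mc$unbranched_synapses$max)
  y_tc <- mc$tc_zone_y_um * NM_PER_UM  # c(lo, hi)
  trees <- list()
  contact_records <- list()
  ledger <- list()
  spacing <- 2000
  for (i in seq_len(nF)) {
    fid <- sprintf("MOC_%03d", i)
    branched <- is_branched[i]
    n_syn <- if (branched) sample_discrete(1, tab_b) else sample_discrete(1, tab_u)
    # synapse rows
    if (branched) {
      modal <- sample(1:3, 1, prob = mc$branched_row_probs)
      rows <- ifelse(runif(n_syn) < mc$modal_concentration, modal,
                     map_int(seq_len(n_syn), ~ {
                       pr <- mc$branched_row_probs
                       pr[modal] <- 0
                       sample(1:3, 1, prob = pr / sum(pr))
                     }))
    } else {
      modal <- NA_integer_
      rows <- sample(1:3, n_syn, replace = TRUE, prob = mc$unbranched_row_probs)
    }
    x0 <- runif(1, 2, nC - 2) * p
    cols <- pmin(nC, pmax(1, round(x0 / p) + 1 + round(rnorm(n_syn, 0, 1.5))))
    z_run <- 10000 + rnorm(1, 0, 1000)
    tb <- new_tree_builder()
    stem <- segment_nodes(c(x0, -30000, z_run), c(x0, -18000, z_run), spacing,
                          0, lat$node_sd_nm)
    stem_ids <- tb_add_chain(tb, stem)
    fork <- stem_ids[length(stem_ids)]
    n_cross <- if (branched) 2L + as.integer(runif(1) < mc$extra_crossing_prob) else 1L
    # split synapses over crossing branches
    br_of_syn <- if (n_cross == 1) rep(1L, n_syn) else
      sort(sample(seq_len(n_cross), n_syn, replace = TRUE))
    hub_ids <- integer(n_cross)
    branch_x <- x0 + (seq_len(n_cross) - (n_cross + 1) / 2) *
      (if (n_cross > 1) runif(1, 8000, 16000) else 0)
    for (b in seq_len(n_cross)) {
      xb <- branch_x[b]
      seg1 <- segment_nodes(c(x0, -18000, z_run), c(xb, -16000, z_run), spacing,
                            0, lat$node_sd_nm, drop_first = TRUE)
      ids1 <- tb_add_chain(tb, seg1, attach_to = fork)
      # the crossing: traverses the tunnel slab in one clean sweep
      seg2 <- segment_nodes(c(xb, -16000, z_run), c(xb, -8000, z_run), spacing,
                            0, lat$node_sd_nm, drop_first = TRUE)
      ids2 <- tb_add_chain(tb, seg2, attach_to = ids1[length(ids1)])
      seg3 <- segment_nodes(c(xb, -8000, z_run), c(xb, -2000, 30000), spacing,
                            0, lat$node_sd_nm, drop_first = TRUE)
      ids3 <- tb_add_chain(tb, seg3, attach_to = ids2[length(ids2)])
      hub_ids[b] <- ids3[length(ids3)]
    }
    for (s in seq_len(n_syn)) {
      r <- rows[s]; j <- cols[s]
      k <- lx_key[r, j]
      bouton <- lx_base[k, ] + c(rnorm(2, 0, 200), -500)
      hub <- hub_ids[br_of_syn[s]]
      hub_xyz <- c(branch_x[br_of_syn[s]], -2000, 30000)
      seg <- segment_nodes(hub_xyz, bouton, spacing, 0, lat$node_sd_nm,
                           drop_first = TRUE)
      ids <- tb_add_chain(tb, seg, attach_to = hub)
      contact_records[[length(contact_records) + 1]] <- list(
        fiber_id = fid, target_id = lx_ohc[k], bouton_class = "efferent",
        x = bouton[1], y = bouton[2], z = bouton[3],
        node_id = ids[length(ids)])
    }
    trees[[fid]] <- tb_finish(tb, fid, "MOC", NA_integer_, integer(),
                              config$pitch_nm)
    ledger[[i]] <- tibble(fiber_id = fid, branched = branched,
                          n_crossings = n_cross, n_synapses = n_syn,
                          modal_row = modal)
  }
  contacts <- bind_rows(contact_records)
  pt <- config$pitch_nm
  contacts$x <- round(contacts$x / pt$dx) * pt$dx
  contacts$y <- round(contacts$y / pt$dy) * pt$dy
  contacts$z <- round(contacts$z / pt$dz) * pt$dz
  list(trees = trees, contacts = contacts, ledger_moc = bind_rows(ledger),
       tc_zone = tc_zone(c(0, y_tc[1], 0), c(0, 1, 0),
                         (y_tc[2] - y_tc[1]) / NM_PER_UM))
}

## ---------------------------------------------------------------------------

#' Generate a complete synthetic organ-of-Corti annotation set
#'
#' Seeded end-to-end generation: supporting-cell lattice, type-2 afferent
#' fibers with contacts, and MOC efferent fibers with contacts, plus the
#' ground-truth ledger recording every sampled parameter (the oracle for
#' recovery tests). Identical `config` + `seed` give identical output.
#'
#' @param config an [oc_config()] (or preset name string).
#' @param seed integer seed.
#' @param components which populations to generate (default all).
#' @return list of class `oc_synthesis`: `annotation` ([oc_annotation()]),
#'   `ledger` (list), `tc_zone`.
#' @examples
#' sim <- generate_organ_of_corti(oc_config("cba1"), seed = 1)
#' sim$annotation
#' @export
generate_organ_of_corti <- function(config = oc_config("cba1"), seed = 1,
                                    components = c("lattice", "t2sgn", "moc")) {
  if (is.character(config)) config <- oc_config(config)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  lattice <- generate_lattice(config)
  trees <- lattice$trees
  contacts <- empty_contacts()
  ledger <- list(
    seed = seed, config = config,
    complexes = lattice$ledger_complexes,
    opcs = lattice$ledger_opcs,
    bm_normal = lattice$bm_normal,
    basal_hint = lattice$basal_hint,
    row_direction = lattice$row_direction)
  zone <- NULL
  if ("t2sgn" %in% components) {
    t2 <- generate_t2sgn(config, lattice)
    trees <- c(trees, t2$trees)
    contacts <- bind_rows(contacts, t2$contacts)
    ledger$fibers <- t2$ledger_fibers
    ledger$attachments <- t2$ledger_attachments
    ledger$census_columns <- t2$census_columns
  }
  if ("moc" %in% components) {
    mo <- generate_moc(config, lattice)
    trees <- c(trees, mo$trees)
    contacts <- bind_rows(contacts, mo$contacts)
    ledger$moc <- mo$ledger_moc
    zone <- mo$tc_zone
  }
  if (is.null(zone)) {
    y_tc <- config$moc$tc_zone_y_um * NM_PER_UM
    zone <- tc_zone(c(0, y_tc[1], 0), c(0, 1, 0), (y_tc[2] - y_tc[1]) / NM_PER_UM)
  }
  ann <- oc_annotation(do.call(voxel_pitch, config$pitch_nm), trees, contacts,
                       provenance = sprintf("synthetic %s seed %d",
                                            config$name, seed))
  structure(list(annotation = ann, ledger = ledger, tc_zone = zone),
            class = "oc_synthesis")
}

#' @export
print.oc_synthesis <- function(x, ...) {
  cat(sprintf("<oc_synthesis> preset %s, seed %d\n", x$ledger$config$name,
              x$ledger$seed))
  print(x$annotation)
  invisible(x)
}
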