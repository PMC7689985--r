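# Reverse-mode gradients for the encoder stages. Mirrors stage_forward()
# exactly; gradients accumulate into a named list parallel to the parameter
# list (missing entries mean zero). Latent-rate gradients are accumulated on
# the mu scale and converted to the free-scalar scale by the caller.

relu_grad <- function(dH, P) dH * (P > 0)

# Backward through one stage. dH_out: named list of gradients w.r.t. the
# stage's final activations. Returns list(grads, dH_in) where dH_in is the
# gradient w.r.t. the stage's dense inputs (NULL for one-hot stages).
stage_backward <- function(stage, params, config, cache, dH_out, mu = NULL) {
  grads <- list()
  add <- function(name, g) {
    grads[[name]] <<- if (is.null(grads[[name]])) g else grads[[name]] + g
  }
  dH <- dH_out
  for (k in rev(seq_along(stage$layer_dims))) {
    onehot_k <- stage$onehot && k == 1
    layer <- cache[[k]]
    dP <- lapply(stats::setNames(nm = stage$classes), function(cl) {
      g <- dH[[cl]]
      if (is.null(g)) g <- matrix(0, stage$n[[cl]], stage$layer_dims[k])
      if (config$activation == "relu") relu_grad(g, layer$P[[cl]]) else g
    })
    dHprev <- NULL
    if (!onehot_k) {
      dHprev <- lapply(stats::setNames(nm = stage$classes), function(cl) {
        matrix(0, nrow(layer$Hd[[cl]]), ncol(layer$Hd[[cl]]))
      })
    }
    for (dir in stage$dirs) {
      wn <- weight_name(stage$id, k, dir$wkey)
      W <- params[[wn]]
      G <- as.matrix(Matrix::crossprod(dir$A, dP[[dir$target]]))
      if (!is.na(dir$mu_type)) {
        if (config$latent_mode == "trainable") {
          X <- layer$Hd[[dir$source]] %*% W
          add(paste0("mu.", dir$mu_type), sum(G * X))
        }
        G <- mu[[dir$mu_type]] * G
      }
      if (onehot_k) {
        add(wn, G)
      } else {
        add(wn, crossprod(layer$Hd[[dir$source]], G))
        dHprev[[dir$source]] <- dHprev[[dir$source]] + G %*% t(W)
      }
    }
    if (!is.null(stage$selfcoef)) {
      for (cl in stage$classes) {
        sn <- self_name(stage$id, k, cl)
        if (onehot_k) {
          add(sn, stage$selfcoef[[cl]] * dP[[cl]])
        } else {
          add(sn, crossprod(stage$selfcoef[[cl]] * layer$Hd[[cl]], dP[[cl]]))
          dHprev[[cl]] <- dHprev[[cl]] +
            (dP[[cl]] %*% t(params[[sn]])) * stage$selfcoef[[cl]]
        }
      }
    }
    if (!onehot_k) {
      if (!is.null(layer$masks)) {
        for (cl in stage$classes) {
          dHprev[[cl]] <- dHprev[[cl]] * layer$masks[[cl]]
        }
      }
      dH <- dHprev
    } else {
      dH <- NULL
    }
  }
  list(grads = grads, dH_in = dH)
}

# Backward through the whole encoder. dZ: named list of gradients w.r.t. the
# final embeddings (chemical/gene at least). Gradients for mu are returned on
# the free-scalar (pre-logistic) scale.
encoder_backward <- function(plan, params, config, caches, dZ, mu) {
  grads <- list()
  dH <- dZ
  for (s in rev(seq_along(plan$stages))) {
    out <- stage_backward(plan$stages[[s]], params, config, caches[[s]], dH, mu)
    for (nm in names(out$grads)) {
      grads[[nm]] <- if (is.null(grads[[nm]])) out$grads[[nm]]
                     else grads[[nm]] + out$grads[[nm]]
    }
    dH <- out$dH_in
  }
  if (config$latent_mode == "trainable") {
    for (ty in plan$types) {
      mn <- paste0("mu.", ty)
      if (!is.null(grads[[mn]])) {
        grads[[mn]] <- grads[[mn]] * mu[[ty]] * (1 - mu[[ty]])
      }
    }
  }
  grads
}
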