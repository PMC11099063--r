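# Stage-level composition of the layer primitives. A model is a list of
# stages; each stage owns uniquely-keyed parameters in the model's flat
# parameter list. Composite stages (residual blocks, inception groups)
# hand-code their backward pass over the primitives they contain.

new_key <- local({
  function(prefix, name) paste0(prefix, ".", name)
})

# ---- parameter initialisation (Glorot uniform, keras default) --------------

glorot <- function(fan_in, fan_out, dims) {
  limit <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -limit, limit), dims)
}

# ---- conv block: conv [+ bn] [+ activation] --------------------------------

mk_conv_block <- function(id, K, Cin, Cout, bn = FALSE, act = "linear",
                          bias = TRUE) {
  list(type = "conv_block", id = id, K = K, Cin = Cin, Cout = Cout,
       bn = bn, act = act, bias = bias, is_conv = TRUE)
}

init_conv_block <- function(st) {
  p <- list()
  p[[new_key(st$id, "W")]] <- glorot(st$K * st$Cin, st$K * st$Cout,
                                     c(st$K, st$Cin, st$Cout))
  if (st$bias) p[[new_key(st$id, "b")]] <- numeric(st$Cout)
  if (st$bn) {
    p[[new_key(st$id, "gamma")]] <- rep(1, st$Cout)
    p[[new_key(st$id, "beta")]] <- numeric(st$Cout)
  }
  p
}

init_conv_state <- function(st) {
  if (!st$bn) return(list())
  s <- list()
  s[[new_key(st$id, "rmean")]] <- numeric(st$Cout)
  s[[new_key(st$id, "rvar")]] <- rep(1, st$Cout)
  s
}

conv_block_fw <- function(st, params, state, X, training) {
  cv <- conv1d_fw(X, params[[new_key(st$id, "W")]],
                  if (st$bias) params[[new_key(st$id, "b")]] else NULL)
  out <- cv$out
  bn_cache <- NULL
  if (st$bn) {
    bn <- bn_fw(out, params[[new_key(st$id, "gamma")]],
                params[[new_key(st$id, "beta")]],
                state[[new_key(st$id, "rmean")]],
                state[[new_key(st$id, "rvar")]], training)
    out <- bn$out
    bn_cache <- bn$cache
    state[[new_key(st$id, "rmean")]] <- bn$rmean
    state[[new_key(st$id, "rvar")]] <- bn$rvar
  }
  ac <- act_fw(out, st$act)
  list(out = ac$out,
       cache = list(conv = cv$cache, bn = bn_cache, act = ac$cache),
       state = state)
}

conv_block_bw <- function(st, params, cache, dOut) {
  g <- list()
  d <- act_bw(cache$act, st$act, dOut)
  if (st$bn) {
    bb <- bn_bw(cache$bn, params[[new_key(st$id, "gamma")]], d)
    g[[new_key(st$id, "gamma")]] <- bb$dgamma
    g[[new_key(st$id, "beta")]] <- bb$dbeta
    d <- bb$dX
  }
  cb <- conv1d_bw(cache$conv, params[[new_key(st$id, "W")]], d)
  g[[new_key(st$id, "W")]] <- cb$dW
  if (st$bias) g[[new_key(st$id, "b")]] <- cb$db
  list(dX = cb$dX, grads = g)
}

# ---- dense stage -----------------------------------------------------------

mk_dense <- function(id, Din, Dout, act = "linear") {
  list(type = "dense", id = id, Din = Din, Dout = Dout, act = act,
       is_conv = FALSE)
}

init_dense <- function(st) {
  p <- list()
  p[[new_key(st$id, "W")]] <- glorot(st$Din, st$Dout, c(st$Din, st$Dout))
  p[[new_key(st$id, "b")]] <- numeric(st$Dout)
  p
}

dense_stage_fw <- function(st, params, X) {
  dn <- dense_fw(X, params[[new_key(st$id, "W")]],
                 params[[new_key(st$id, "b")]])
  ac <- act_fw(dn$out, st$act)
  list(out = ac$out, cache = list(dense = dn$cache, act = ac$cache))
}

dense_stage_bw <- function(st, params, cache, dOut) {
  d <- act_bw(cache$act, st$act, dOut)
  db <- dense_bw(cache$dense, params[[new_key(st$id, "W")]], d)
  g <- list()
  g[[new_key(st$id, "W")]] <- db$dW
  g[[new_key(st$id, "b")]] <- db$db
  list(dX = db$dX, grads = g)
}

# ---- residual block (3 conv-bn sublayers + 1x1 conv-bn shortcut) -----------

mk_resblock <- function(id, Cin, Cout, kernels = c(8, 5, 3)) {
  sub <- list(
    mk_conv_block(new_key(id, "c1"), kernels[1], Cin, Cout, bn = TRUE,
                  act = "relu"),
    mk_conv_block(new_key(id, "c2"), kernels[2], Cout, Cout, bn = TRUE,
                  act = "relu"),
    mk_conv_block(new_key(id, "c3"), kernels[3], Cout, Cout, bn = TRUE,
                  act = "linear")
  )
  sc <- mk_conv_block(new_key(id, "sc"), 1, Cin, Cout, bn = TRUE,
                      act = "linear")
  list(type = "resblock", id = id, sub = sub, shortcut = sc,
       Cin = Cin, Cout = Cout, is_conv = TRUE, n_conv = 3L)
}

init_resblock <- function(st) {
  c(do.call(c, lapply(st$sub, init_conv_block)), init_conv_block(st$shortcut))
}

init_resblock_state <- function(st) {
  c(do.call(c, lapply(st$sub, init_conv_state)),
    init_conv_state(st$shortcut))
}

resblock_fw <- function(st, params, state, X, training) {
  h <- X
  caches <- vector("list", length(st$sub))
  for (i in seq_along(st$sub)) {
    r <- conv_block_fw(st$sub[[i]], params, state, h, training)
    h <- r$out; caches[[i]] <- r$cache; state <- r$state
  }
  sc <- conv_block_fw(st$shortcut, params, state, X, training)
  state <- sc$state
  s <- h + sc$out
  ac <- act_fw(s, "relu")
  list(out = ac$out,
       cache = list(sub = caches, sc = sc$cache, act = ac$cache),
       state = state)
}

resblock_bw <- function(st, params, cache, dOut) {
  d <- act_bw(cache$act, "relu", dOut)
  g <- list()
  # main branch
  dm <- d
  for (i in rev(seq_along(st$sub))) {
    r <- conv_block_bw(st$sub[[i]], params, cache$sub[[i]], dm)
    g <- c(g, r$grads)
    dm <- r$dX
  }
  # shortcut branch
  rs <- conv_block_bw(st$shortcut, params, cache$sc, d)
  g <- c(g, rs$grads)
  list(dX = dm + rs$dX, grads = g)
}

# ---- inception module & residual inception group ---------------------------

mk_incep_module <- function(id, Cin, nf = 32, kernels = c(39, 19, 9)) {
  use_bottleneck <- Cin > 1
  Cb <- if (use_bottleneck) nf else Cin
  list(
    type = "incep_module", id = id, Cin = Cin, nf = nf,
    use_bottleneck = use_bottleneck,
    bottleneck = if (use_bottleneck) {
      mk_conv_block(new_key(id, "bot"), 1, Cin, nf, bn = FALSE,
                    act = "linear", bias = FALSE)
    },
    convs = lapply(seq_along(kernels), function(i) {
      mk_conv_block(new_key(id, paste0("k", i)), kernels[i], Cb, nf,
                    bn = FALSE, act = "linear", bias = FALSE)
    }),
    pool_conv = mk_conv_block(new_key(id, "pc"), 1, Cin, nf, bn = FALSE,
                              act = "linear", bias = FALSE),
    Cout = 4L * nf
  )
}

init_incep_module <- function(st) {
  p <- list()
  if (st$use_bottleneck) p <- c(p, init_conv_block(st$bottleneck))
  p <- c(p, do.call(c, lapply(st$convs, init_conv_block)),
         init_conv_block(st$pool_conv))
  # concat-wide batch norm
  p[[new_key(st$id, "gamma")]] <- rep(1, st$Cout)
  p[[new_key(st$id, "beta")]] <- numeric(st$Cout)
  p
}

init_incep_module_state <- function(st) {
  s <- list()
  s[[new_key(st$id, "rmean")]] <- numeric(st$Cout)
  s[[new_key(st$id, "rvar")]] <- rep(1, st$Cout)
  s
}

incep_module_fw <- function(st, params, state, X, training) {
  if (st$use_bottleneck) {
    bt <- conv_block_fw(st$bottleneck, params, state, X, training)
    h <- bt$out; bt_cache <- bt$cache
  } else {
    h <- X; bt_cache <- NULL
  }
  branches <- vector("list", length(st$convs))
  outs <- vector("list", length(st$convs) + 1L)
  for (i in seq_along(st$convs)) {
    r <- conv_block_fw(st$convs[[i]], params, state, h, training)
    branches[[i]] <- r$cache
    outs[[i]] <- r$out
  }
  mp <- maxpool_same3_fw(X)
  pc <- conv_block_fw(st$pool_conv, params, state, mp$out, training)
  outs[[length(outs)]] <- pc$out
  d <- dim(X)
  cat_out <- array(0, c(d[1], d[2], st$Cout))
  off <- 0L
  for (o in outs) {
    cat_out[, , off + seq_len(st$nf)] <- o
    off <- off + st$nf
  }
  bn <- bn_fw(cat_out, params[[new_key(st$id, "gamma")]],
              params[[new_key(st$id, "beta")]],
              state[[new_key(st$id, "rmean")]],
              state[[new_key(st$id, "rvar")]], training)
  state[[new_key(st$id, "rmean")]] <- bn$rmean
  state[[new_key(st$id, "rvar")]] <- bn$rvar
  ac <- act_fw(bn$out, "relu")
  list(out = ac$out,
       cache = list(bt = bt_cache, branches = branches, mp = mp$cache,
                    pc = pc$cache, bn = bn$cache, act = ac$cache,
                    in_dims = d),
       state = state)
}

incep_module_bw <- function(st, params, cache, dOut) {
  g <- list()
  d <- act_bw(cache$act, "relu", dOut)
  bb <- bn_bw(cache$bn, params[[new_key(st$id, "gamma")]], d)
  g[[new_key(st$id, "gamma")]] <- bb$dgamma
  g[[new_key(st$id, "beta")]] <- bb$dbeta
  dcat <- bb$dX
  nf <- st$nf
  dX <- array(0, cache$in_dims)
  dh <- NULL
  for (i in seq_along(st$convs)) {
    dbr <- array(dcat[, , (i - 1L) * nf + seq_len(nf)],
                 c(cache$in_dims[1], cache$in_dims[2], nf))
    r <- conv_block_bw(st$convs[[i]], params, cache$branches[[i]], dbr)
    g <- c(g, r$grads)
    dh <- if (is.null(dh)) r$dX else dh + r$dX
  }
  dpc <- array(dcat[, , 3L * nf + seq_len(nf)],
               c(cache$in_dims[1], cache$in_dims[2], nf))
  rp <- conv_block_bw(st$pool_conv, params, cache$pc, dpc)
  g <- c(g, rp$grads)
  dX <- dX + maxpool_same3_bw(cache$mp, rp$dX)
  if (st$use_bottleneck) {
    rb <- conv_block_bw(st$bottleneck, params, cache$bt, dh)
    g <- c(g, rb$grads)
    dX <- dX + rb$dX
  } else {
    dX <- dX + dh
  }
  list(dX = dX, grads = g)
}

mk_incepgroup <- function(id, Cin, nf = 32, n_modules = 3L,
                          kernels = c(39, 19, 9)) {
  modules <- vector("list", n_modules)
  cin <- Cin
  for (i in seq_len(n_modules)) {
    modules[[i]] <- mk_incep_module(new_key(id, paste0("m", i)), cin, nf,
                                    kernels)
    cin <- modules[[i]]$Cout
  }
  sc <- mk_conv_block(new_key(id, "sc"), 1, Cin, 4L * nf, bn = TRUE,
                      act = "linear")
  list(type = "incepgroup", id = id, modules = modules, shortcut = sc,
       Cin = Cin, Cout = 4L * nf, is_conv = TRUE,
       n_conv = as.integer(n_modules))
}

init_incepgroup <- function(st) {
  c(do.call(c, lapply(st$modules, init_incep_module)),
    init_conv_block(st$shortcut))
}

init_incepgroup_state <- function(st) {
  c(do.call(c, lapply(st$modules, init_incep_module_state)),
    init_conv_state(st$shortcut))
}

incepgroup_fw <- function(st, params, state, X, training) {
  h <- X
  caches <- vector("list", length(st$modules))
  for (i in seq_along(st$modules)) {
    r <- incep_module_fw(st$modules[[i]], params, state, h, training)
    h <- r$out; caches[[i]] <- r$cache; state <- r$state
  }
  sc <- conv_block_fw(st$shortcut, params, state, X, training)
  state <- sc$state
  ac <- act_fw(h + sc$out, "relu")
  list(out = ac$out,
       cache = list(modules = caches, sc = sc$cache, act = ac$cache),
       state = state)
}

incepgroup_bw <- function(st, params, cache, dOut) {
  d <- act_bw(cache$act, "relu", dOut)
  g <- list()
  dm <- d
  for (i in rev(seq_along(st$modules))) {
    r <- incep_module_bw(st$modules[[i]], params, cache$modules[[i]], dm)
    g <- c(g, r$grads)
    dm <- r$dX
  }
  rs <- conv_block_bw(st$shortcut, params, cache$sc, d)
  g <- c(g, rs$grads)
  list(dX = dm + rs$dX, grads = g)
}

# ---- simple stages ---------------------------------------------------------

mk_dropout <- function(id, rate) {
  list(type = "dropout", id = id, rate = rate, is_conv = FALSE)
}
mk_pool <- function(id, pool, kind) {
  list(type = "pool", id = id, pool = pool, kind = kind, is_conv = FALSE)
}
mk_gap <- function(id) list(type = "gap", id = id, is_conv = FALSE)
mk_flatten <- function(id) list(type = "flatten", id = id, is_conv = FALSE)

# ---- generic stage dispatch ------------------------------------------------

stage_init_params <- function(st) {
  switch(st$type,
         conv_block = init_conv_block(st),
         dense = init_dense(st),
         resblock = init_resblock(st),
         incepgroup = init_incepgroup(st),
         list())
}

stage_init_state <- function(st) {
  switch(st$type,
         conv_block = init_conv_state(st),
         resblock = init_resblock_state(st),
         incepgroup = init_incepgroup_state(st),
         list())
}

stage_fw <- function(st, params, state, X, training) {
  switch(
    st$type,
    conv_block = conv_block_fw(st, params, state, X, training),
    resblock = resblock_fw(st, params, state, X, training),
    incepgroup = incepgroup_fw(st, params, state, X, training),
    dense = c(dense_stage_fw(st, params, X), list(state = state)),
    dropout = {
      r <- dropout_fw(X, st$rate, training)
      list(out = r$out, cache = r$cache, state = state)
    },
    pool = {
      r <- pool_fw(X, st$pool, st$kind)
      list(out = r$out, cache = r$cache, state = state)
    },
    gap = {
      r <- gap_fw(X)
      list(out = r$out, cache = r$cache, state = state)
    },
    flatten = {
      r <- flatten_fw(X)
      list(out = r$out, cache = r$cache, state = state)
    },
    stop("unknown stage type: ", st$type)
  )
}

stage_bw <- function(st, params, cache, dOut) {
  switch(
    st$type,
    conv_block = conv_block_bw(st, params, cache, dOut),
    resblock = resblock_bw(st, params, cache, dOut),
    incepgroup = incepgroup_bw(st, params, cache, dOut),
    dense = dense_stage_bw(st, params, cache, dOut),
    dropout = list(dX = dropout_bw(cache, dOut), grads = list()),
    pool = list(dX = pool_bw(cache, st$pool, st$kind, dOut), grads = list()),
    gap = list(dX = gap_bw(cache, dOut), grads = list()),
    flatten = list(dX = flatten_bw(cache, dOut), grads = list()),
    stop("unknown stage type: ", st$type)
  )
}

# ---- whole-model forward/backward -----------------------------------------

# Forward through all stages. Returns logits, per-stage caches and outputs,
# and the updated BN running state.
model_forward <- function(model, X, training = FALSE, collect = FALSE) {
  h <- X
  if (length(dim(h)) == 2 && model$takes_3d) {
    h <- array(h, c(nrow(h), ncol(h), 1L))
  }
  caches <- vector("list", length(model$stages))
  outs <- if (collect) vector("list", length(model$stages)) else NULL
  state <- model$state
  for (i in seq_along(model$stages)) {
    r <- stage_fw(model$stages[[i]], model$params, state, h, training)
    h <- r$out; caches[[i]] <- r$cache; state <- r$state
    if (collect) outs[[i]] <- h
  }
  list(logits = h, caches = caches, outs = outs, state = state)
}

# Backward from dLogits down to stage `stop_at + 1` (0 = all the way).
# Returns accumulated parameter gradients and the gradient arriving at the
# output of stage `stop_at` (the input when stop_at = 0).
model_backward <- function(model, caches, dLogits, stop_at = 0L) {
  d <- dLogits
  grads <- list()
  for (i in rev(seq_along(model$stages))) {
    if (i <= stop_at) break
    r <- stage_bw(model$stages[[i]], model$params, caches[[i]], d)
    grads <- c(grads, r$grads)
    d <- r$dX
  }
  list(grads = grads, dX = d)
}

# Forward from the output of stage `from` (activation A) to the logits,
# in eval mode. Used by the grad-CAM finite-difference oracle.
model_forward_from <- function(model, from, A) {
  h <- A
  state <- model$state
  for (i in seq_along(model$stages)) {
    if (i <= from) next
    r <- stage_fw(model$stages[[i]], model$params, state, h, FALSE)
    h <- r$out
  }
  h
}
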