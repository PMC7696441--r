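test_that("the 64-sample spec has the canonical topology and shapes", {
  spec <- build_model_spec(64, 3)
  kinds <- vapply(spec$layers, `[[`, character(1), "kind")
  expect_equal(sum(kinds == "conv1d"), 4L)
  expect_equal(sum(kinds == "maxpool1d"), 2L)
  expect_equal(sum(kinds == "dense"), 3L)
  # ReLU on layers 1, 2, 4, 6, 7, 8 of the nine parameterized/pooling layers
  # (the flatten/dropout plumbing carries no activation)
  acts <- vapply(spec$layers,
                 function(l) if (is.null(l$activation)) "" else l$activation,
                 character(1))
  named <- which(kinds %in% c("conv1d", "maxpool1d", "dense"))
  expect_equal(acts[named],
               c("relu", "relu", "", "relu", "", "relu", "relu", "relu",
                 "softmax"))
  # feature map after the first pooling stage: 32 positions x 64 channels
  pool1 <- which(kinds == "maxpool1d")[1]
  expect_equal(spec$shapes[[pool1]], list(length = 32L, channels = 64L))
  # dense head: 300, 100, n_classes
  expect_equal(vapply(spec$layers[kinds == "dense"], `[[`, integer(1), "units"),
               c(300L, 100L, 3L))
  # batch norm only after the first convolution by default
  expect_equal(vapply(spec$layers[kinds == "conv1d"], `[[`, logical(1),
                      "batch_norm"),
               c(TRUE, FALSE, FALSE, FALSE))
})

test_that("the 12-sample experimental variant keeps the topology", {
  spec <- build_model_spec(12, 5)
  kinds <- vapply(spec$layers, `[[`, character(1), "kind")
  expect_equal(sum(kinds == "conv1d"), 4L)
  expect_equal(spec$layers[[length(spec$layers)]]$units, 5L)
  # 12 -> 6 -> 3 positions through the two halvings
  expect_equal(spec$shapes[[length(spec$layers)]]$width, 5L)
  flat <- which(kinds == "flatten")
  expect_equal(spec$shapes[[flat]]$width, 3L * 32L)
})

test_that("too-short inputs fail the pooling constraint", {
  expect_error(build_model_spec(4, 3), "pooling")
  expect_error(build_model_spec(64, 1), "at least 2")
})

test_that("parameter counts match independent layer-by-layer arithmetic", {
  # hand count for the (64, 3) network:
  #   conv1  1 -> 32:   32*(3*1)  + 32  =    128, batch norm + 2*32 =  64
  #   conv2 32 -> 64:   64*(3*32) + 64  =   6208
  #   conv3 64 -> 64:   64*(3*64) + 64  =  12352
  #   conv4 64 -> 32:   32*(3*64) + 32  =   6176
  #   flatten: 16 positions * 32 channels = 512
  #   dense 512 -> 300: 512*300 + 300   = 153900
  #   dense 300 -> 100: 300*100 + 100   =  30100
  #   dense 100 ->   3: 100*3   + 3     =    303
  hand <- (32 * 3 + 32) + 2 * 32 +
    (64 * 3 * 32 + 64) + (64 * 3 * 64 + 64) + (32 * 3 * 64 + 32) +
    (512 * 300 + 300) + (300 * 100 + 100) + (100 * 3 + 3)
  expect_identical(hand, 209231)
  expect_identical(count_parameters(build_model_spec(64, 3)), 209231L)
  # single-layer closed forms
  expect_identical(count_parameters(build_model_spec(64, 3)) -
                     count_parameters(build_model_spec(64, 2)),
                   100L + 1L)  # one more softmax unit: 100 weights + 1 bias
})

test_that("the length-preserving pooling variant is available", {
  spec <- build_model_spec(64, 3, pooling = "slide")
  kinds <- vapply(spec$layers, `[[`, character(1), "kind")
  pool1 <- which(kinds == "maxpool1d")[1]
  # kernel 3, stride 1, valid: 64 -> 62
  expect_equal(spec$shapes[[pool1]]$length, 62L)
  expect_equal(spec$layers[[pool1]]$kernel, 3L)
  expect_equal(spec$layers[[pool1]]$stride, 1L)
})

test_that("batch-norm placement options change the parameter count correctly", {
  base <- count_parameters(build_model_spec(64, 3, batch_norm = "none"))
  first <- count_parameters(build_model_spec(64, 3, batch_norm = "first"))
  all_bn <- count_parameters(build_model_spec(64, 3, batch_norm = "all"))
  expect_identical(first - base, 2L * 32L)
  expect_identical(all_bn - base, 2L * (32L + 64L + 64L + 32L))
})
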