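# A small rendered two-synapse experiment shared by the pipeline and
# acceptance tests: two 2-site AZs in opposite quadrants of a 32x32
# movie, 40 AP at 10 Hz, with matching square ROIs.
makeTestExperiment <- function() {
  proto <- StimulusProtocol(40, 10, 0.05, nBaselineFrames = 10L)
  az1 <- makeAZ(2, 150, c(0.5, 0.5), seed = 1)
  az2 <- makeAZ(2, 150, c(0.4, 0.4), seed = 2)
  ev1 <- sampleEvents(az1, proto, seed = 3)
  ev2 <- sampleEvents(az2, proto, seed = 4)
  ev1$x_nm <- ev1$x_nm + 8 * 87;  ev1$y_nm <- ev1$y_nm + 8 * 87
  ev2$x_nm <- ev2$x_nm + 24 * 87; ev2$y_nm <- ev2$y_nm + 24 * 87
  ev <- rbind(ev1, ev2)
  mv <- renderMovie(ev, 130, photonsPerEvent = 800, background = 8,
                    shape = c(32, 32), nFrames = 92, seed = 5)
  half <- 16 * 87
  full <- 32 * 87
  rois <- RoiSet(c("az1", "az2"),
                 list(cbind(c(0, half, half, 0), c(0, 0, half, half)),
                      cbind(c(half, full, full, half),
                            c(half, half, full, full))))
  list(movie = mv, rois = rois, protocol = proto, truth = ev)
}
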