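# Shared fixtures. Everything is generated in code; expensive objects are
# built once per test run and cached in this environment.

.fixtures <- new.env(parent = emptyenv())

standardDesign <- function() MicrochannelDesign(channelLength = 10,
                                                nElectrodes = 8, pitch = 1)

fig2cFiber <- function() FiberSpec(velocity = 13.3, amplitude = 55,
                                   width = 0.22)

# physiological width-velocity coupling used when drawing test fibers
widthForVelocity <- function(v) pmin(0.3, pmax(0.03, 0.05 + 1.2 / v))

# a small but full-rank SR sweep: 4 designs varying length, electrode count
# and pitch, crossed with widths x velocities x SNRs, 10 repetitions
testSweepDataset <- function() {
  if (!is.null(.fixtures$sweep)) return(.fixtures$sweep)
  designs <- list(
    MicrochannelDesign(10, 8, 1),
    MicrochannelDesign(6, 5, 1),
    MicrochannelDesign(10, 6, 1.33),
    MicrochannelDesign(4, 3, 0.67))
  rs <- simulateSrSweep(designs, widths = c(0.15, 0.25),
                        velocities = c(8, 25, 50), snrDbs = c(5, 12, 25),
                        nRepetitions = 10, fs = 5e5, seed = 2024)
  .fixtures$sweep <- srDataset(rs)
  .fixtures$sweep
}

# default inhibition session (bench schedule, scaled to 3 light cycles)
testInhibitionSession <- function() {
  if (!is.null(.fixtures$inhib)) return(.fixtures$inhib)
  rec <- simulateInhibitionSession(
    standardDesign(),
    list(FiberSpec(12, 45, 0.2), FiberSpec(2, 18, 0.45)),
    StimulusProtocol(repetitions = 55, period = 3),
    IlluminationProtocol(), noiseSnrDb = 30, seed = 401)
  .fixtures$inhib <- list(
    rec = rec,
    nsd = nsdSeries(rec, nControl = 10, maskElectrodes = 4:6))
  .fixtures$inhib
}

nullCoupling <- function()
  utils::modifyList(couplingDefaults(),
                    list(cSlow = 0, cFast = 0, blockDepth = 0,
                         velocityTempCoeff = 0))
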