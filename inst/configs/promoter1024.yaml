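# Conditional promoter-like sequence design at full length: 1024-bp
# sequences centered on the TSS with a per-position initiation-signal
# conditioning track (synthetic records generated by
# generatePromoterLike; real CAGE data handling is out of scope). The
# dilated convolutional stack stands in for the full promoter-design
# architecture. Long-running; intended for GPU-class budgets.
#   ddsm train --config promoter1024.yaml --out runs/promoter
#   ddsm sample --config promoter1024.yaml \
#       --model runs/promoter/model.rds --n 100 --out runs/promoter
#   ddsm likelihood --config promoter1024.yaml \
#       --model runs/promoter/model.rds --n 16 --out runs/promoter
task: promoter-synthetic
seed: 1
L: 1024
channels: 128
batchSize: 64
lr: 0.0005
steps: 100000
cacheTimes: 100
cachePerCell: 10000
nSamplerSteps: 200
dilation: 4
t0: 0.01
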