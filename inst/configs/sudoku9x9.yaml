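# Full-scale 9x9 Sudoku generation/solving run. This configuration is
# faithful to the full task (81 cells, k = 9, 20-block relational
# transformer with the 27-dimensional relative positional encoding) and
# is intended for long GPU-class training; it is far beyond interactive
# CPU budgets. Run with:
#   ddsm cache-build --config sudoku9x9.yaml --out runs/sudoku9x9
#   ddsm train --config sudoku9x9.yaml --cache runs/sudoku9x9/cache.rds \
#       --out runs/sudoku9x9
#   ddsm sample --config sudoku9x9.yaml \
#       --model runs/sudoku9x9/model.rds --dilation 8 --n 100 \
#       --out runs/sudoku9x9
task: sudoku
seed: 1
nBlocks: 20
dModel: 256
batchSize: 256
lr: 0.0002
steps: 200000
cacheTimes: 100
cachePerCell: 10000
nSamplerSteps: 400
dilation: 8
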