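# Small convolutional classifier: 10 filters of width 21, dense layer
# with 5 hidden units, softmax output over the two conditions.
seed: 1
loss: categorical_crossentropy
optimizer: {name: adam, learning_rate: 0.001}
training: {batch_size: 64, epochs: 30, patience: 10}
architecture:
  - {type: conv, filters: 10, width: 21}
  - {type: relu}
  - {type: dense, units: 5}
  - {type: relu}
  - {type: dense, units: 2}
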