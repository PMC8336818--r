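wrist
hand
torso
arm
forearm
leg
thigh
neck
throat
head
stomach
abdomen
chest
face
skin
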