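# Words retained for analysis even when present on the exclusion list:
# they can refer to body parts, mechanisms of injury, or injurious objects,
# all of which carry signal in triage narratives. This membership is a
# design artifact of the package; extend it to suit your corpus.
# body parts
back
face
feet
foot
head
hand
arm
leg
eye
ear
finger
thumb
knee
ankle
wrist
shoulder
hip
chest
neck
scalp
rib
# mechanisms of injury
cut
fall
fell
burn
hit
crush
struck
caught
slipped
twisted
# injurious objects
saw
hammer
knife
nail
glass
ladder
machine
drill
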