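item,score
dizziness_transfers,3
lightheadedness_upright,4
vision_blurring,2
fatigue_meals,2
headache_standing,1
goosebumps,0
fainting,2
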