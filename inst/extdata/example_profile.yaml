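# Example calibration profile for a top-view hamster recording
# (published threshold set; pairs listed min-first after sorting).
# hsv_scale declares the scale of the bounds below: "opencv" means
# H in [0, 180] and S, V in [0, 255].
hsv_scale: opencv
body.h_min: 60
body.h_max: 95
body.s_min: 0
body.s_max: 30
body.v_min: 75
body.v_max: 125
eye.h_min: 30
eye.h_max: 65
eye.s_min: 50
eye.s_max: 100
eye.v_min: 10
eye.v_max: 40
ax: 680
ay: 150
alpha_th: 10200
crop.mx: 350
crop.my: 0
crop.rx: 1370
crop.ry: 880
fps: 60
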