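units:
  voltage: mV
  time: ms
  conductance: nS
  capacitance: pF
  current: pA
  temperature: degC
cell:
  c_soma: 90.0
  c_axon: 15.0
  g_couple: 15.0
  temperature: 30.0
  g_soma:
    Na: 700.0
    Kdr: 470.0
    A: 30.0
    Kv1: 41.7
    T: 18.0
    H: 0.4
    leak: 1.089929
  g_axon:
    Na: 800.0
    Kdr: 500.0
    A: 0.0
    Kv1: 23.0
    T: 0.0
    H: 0.0
    leak: 0.2
channels:
  Na:
    name: Na
    p: 3
    q: 1
    v_half_act: -42.8
    slope_act: 5.0
    tau_act:
    - 0.04
    - 0.25
    - -40.0
    - 12.0
    - 12.0
    v_half_inact: -50.0
    slope_inact: -6.0
    tau_inact:
    - 0.4
    - 6.0
    - -55.0
    - 9.0
    - 9.0
    e_rev: 50.0
    q10: 3.0
    t_ref: 30.0
  Kdr:
    name: Kdr
    p: 4
    q: 0
    v_half_act: -33.0
    slope_act: 9.0
    tau_act:
    - 1.5
    - 43.0
    - -50.0
    - 20.0
    - 20.0
    v_half_inact: .na.real
    slope_inact: .na.real
    tau_inact: []
    e_rev: -90.0
    q10: 3.0
    t_ref: 30.0
  A:
    name: A
    p: 4
    q: 1
    v_half_act: -45.0
    slope_act: 8.0
    tau_act:
    - 0.4
    - 1.2
    - -50.0
    - 15.0
    - 15.0
    v_half_inact: -78.0
    slope_inact: -6.0
    tau_inact:
    - 20.0
    - 60.0
    - -78.0
    - 10.0
    - 10.0
    e_rev: -90.0
    q10: 3.0
    t_ref: 30.0
  Kv1:
    name: Kv1
    p: 1
    q: 1
    v_half_act: -44.9
    slope_act: 4.0
    tau_act:
    - 1.0
    - 8.0
    - -48.0
    - 15.0
    - 15.0
    v_half_inact: -65.0
    slope_inact: -5.0
    tau_inact:
    - 150.0
    - 240.0
    - -55.0
    - 15.0
    - 15.0
    e_rev: -90.0
    q10: 3.0
    t_ref: 30.0
  T:
    name: T
    p: 2
    q: 1
    v_half_act: -57.0
    slope_act: 6.2
    tau_act:
    - 0.6
    - 18.0
    - -68.0
    - 16.7
    - 18.2
    v_half_inact: -81.0
    slope_inact: -4.0
    tau_inact:
    - 10.0
    - 200.0
    - -88.0
    - 10.0
    - 16.0
    e_rev: 120.0
    q10: 3.0
    t_ref: 30.0
  H:
    name: H
    p: 0
    q: 1
    v_half_act: .na.real
    slope_act: .na.real
    tau_act: []
    v_half_inact: -80.0
    slope_inact: -6.0
    tau_inact:
    - 200.0
    - 1000.0
    - -80.0
    - 15.0
    - 15.0
    e_rev: -43.0
    q10: 3.0
    t_ref: 30.0
  leak:
    name: leak
    p: 0
    q: 0
    v_half_act: .na.real
    slope_act: .na.real
    tau_act: []
    v_half_inact: .na.real
    slope_inact: .na.real
    tau_inact: []
    e_rev: -80.41621
    q10: 1.0
    t_ref: 30.0
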