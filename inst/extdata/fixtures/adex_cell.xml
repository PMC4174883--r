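<Lems>
  <!-- Adaptive exponential integrate-and-fire cell with two regimes:
       normal integration, and a refractory phase entered on spike whose
       OnEntry applies the reset and the adaptation increment. Standard
       reference parameterization (tonic firing). -->
  <Include file="lems_core_types.xml"/>
  <Target component="sim1"/>

  <adExIaFCell id="adexTonic" C="281 pF" gL="30 nS" EL="-70.6 mV"
               VT="-50.4 mV" delT="2 mV" Vr="-70.6 mV" vPeak="-40.4 mV"
               a="4 nS" b="80.5 pA" tauw="144 ms" refract="5 ms">
    <pulseGenerator id="stim" delay="50 ms" duration="200 ms"
                    amplitude="0.75 nA"/>
  </adExIaFCell>

  <Simulation id="sim1" length="300 ms" step="0.025 ms" target="adexTonic">
    <OutputFile id="of1" fileName="adex_cell.dat">
      <OutputColumn id="v" quantity="v"/>
      <OutputColumn id="w" quantity="w"/>
    </OutputFile>
    <EventOutputFile id="ev1" fileName="adex_cell.events"/>
  </Simulation>
</Lems>
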