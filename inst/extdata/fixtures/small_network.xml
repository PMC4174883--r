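<Lems>
  <!-- Three-cell mutually inhibitory ring (a lumped pacemaker pair plus
       two follower neurons) built from adaptive exponential cells and
       blocking/plastic synapses, with fast and slow inhibitory
       connections carrying distinct delays and weights. -->
  <Include file="lems_core_types.xml"/>
  <Target component="sim1"/>

  <adExIaFCell id="pacemaker" C="281 pF" gL="30 nS" EL="-70.6 mV"
               VT="-50.4 mV" delT="2 mV" Vr="-70.6 mV" vPeak="-40.4 mV"
               a="4 nS" b="80.5 pA" tauw="144 ms" refract="5 ms">
    <pulseGenerator id="drive" delay="10 ms" duration="280 ms"
                    amplitude="0.8 nA"/>
  </adExIaFCell>

  <adExIaFCell id="follower" C="281 pF" gL="30 nS" EL="-70.6 mV"
               VT="-50.4 mV" delT="2 mV" Vr="-70.6 mV" vPeak="-40.4 mV"
               a="4 nS" b="80.5 pA" tauw="144 ms" refract="5 ms">
    <pulseGenerator id="drive" delay="10 ms" duration="280 ms"
                    amplitude="0.65 nA"/>
  </adExIaFCell>

  <blockingPlasticSynapse id="inhFast" gbase="8 nS" erev="-80 mV"
                          tauDecay="5 ms">
    <blockMechanism type="voltageConcDepBlockMechanism"
                    blockConcentration="0 mM" scalingConc="1.9 mM"
                    scalingVolt="16.13 mV"/>
    <plasticityMechanism type="tsodyksMarkramDepFacMechanism"
                         initReleaseProb="0.5" tauRec="120 ms"
                         tauFac="10 ms"/>
  </blockingPlasticSynapse>

  <blockingPlasticSynapse id="inhSlow" gbase="4 nS" erev="-80 mV"
                          tauDecay="50 ms">
    <blockMechanism type="voltageConcDepBlockMechanism"
                    blockConcentration="0 mM" scalingConc="1.9 mM"
                    scalingVolt="16.13 mV"/>
    <plasticityMechanism type="tsodyksMarkramDepFacMechanism"
                         initReleaseProb="0.5" tauRec="120 ms"
                         tauFac="10 ms"/>
  </blockingPlasticSynapse>

  <network id="ring">
    <population id="abpd" size="1" component="pacemaker"/>
    <population id="lp" size="1" component="follower"/>
    <population id="py" size="1" component="follower"/>
    <explicitConnection id="c1" from="abpd/pacemaker[0]"
                        to="lp/follower[0]" synapse="inhFast"
                        delay="1 ms" weight="1"/>
    <explicitConnection id="c2" from="abpd/pacemaker[0]"
                        to="py/follower[0]" synapse="inhSlow"
                        delay="2 ms" weight="0.5"/>
    <explicitConnection id="c3" from="lp/follower[0]"
                        to="py/follower[0]" synapse="inhFast"
                        delay="1 ms" weight="1"/>
    <explicitConnection id="c4" from="lp/follower[0]"
                        to="abpd/pacemaker[0]" synapse="inhSlow"
                        delay="2 ms" weight="0.5"/>
    <explicitConnection id="c5" from="py/follower[0]"
                        to="lp/follower[0]" synapse="inhFast"
                        delay="1 ms" weight="1"/>
    <explicitConnection id="c6" from="py/follower[0]"
                        to="abpd/pacemaker[0]" synapse="inhFast"
                        delay="1 ms" weight="1"/>
  </network>

  <Simulation id="sim1" length="300 ms" step="0.025 ms" target="ring">
    <OutputFile id="of1" fileName="small_network.dat">
      <OutputColumn id="vAB" quantity="abpd/pacemaker[0]/v"/>
      <OutputColumn id="vLP" quantity="lp/follower[0]/v"/>
      <OutputColumn id="vPY" quantity="py/follower[0]/v"/>
    </OutputFile>
    <EventOutputFile id="ev1" fileName="small_network.events"/>
  </Simulation>
</Lems>
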