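<?xml version="1.0" encoding="UTF-8"?>
<clinical_studies>
  <clinical_study>
    <id_info>
      <nct_id>NCT01000001</nct_id>
    </id_info>
    <brief_title>A Multicentre Trial in Hemophilia A</brief_title>
    <overall_status>Recruiting</overall_status>
    <start_date>May 12, 2016</start_date>
    <completion_date>March 30, 2020</completion_date>
    <condition>Hemophilia A</condition>
    <location>
      <facility>
        <name>Berlin University Hospital</name>
        <address>
          <city>Berlin</city>
          <zip>10117</zip>
          <country>Germany</country>
        </address>
      </facility>
    </location>
    <location>
      <facility>
        <name>Paris Reference Centre</name>
        <address>
          <city>Paris</city>
          <country>France</country>
        </address>
      </facility>
    </location>
    <location>
      <facility>
        <name>Milan Coagulation Institute</name>
        <address>
          <city>Milan</city>
          <country>Italy</country>
        </address>
      </facility>
    </location>
  </clinical_study>
  <clinical_study>
    <id_info>
      <nct_id>NCT01000002</nct_id>
    </id_info>
    <brief_title>Early Reperfusion After Myocardial Infarction</brief_title>
    <overall_status>Completed</overall_status>
    <start_date>January 5, 2015</start_date>
    <completion_date>September 1, 2018</completion_date>
    <condition>Myocardial Infarction</condition>
    <location>
      <facility>
        <name>University of Leeds</name>
        <address>
          <city>Leeds</city>
          <zip>LS184AB</zip>
          <country>United Kingdom</country>
        </address>
      </facility>
    </location>
    <location>
      <facility>
        <name>Münster University Hospital</name>
        <address>
          <city>Münster</city>
          <zip>48149</zip>
          <country>Germany</country>
        </address>
      </facility>
    </location>
  </clinical_study>
</clinical_studies>
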